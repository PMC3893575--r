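#' Construct a vocal motor command
#'
#' A command is a 9-dimensional vector: seven articulatory positions (jaw /
#' tongue-body / local deformation axes, range \[-3, 3\]), glottal pressure
#' and voicing (range \[-1, 1\]). Out-of-range values are clipped. The
#' resting configuration has all articulators at 0 and pressure = voicing =
#' -0.25, which does not phonate.
#'
#' @param art numeric vector of 7 articulatory positions.
#' @param pressure,voicing scalars; phonation requires both to be positive.
#' @param config a [vd_config()] list.
#' @return A named numeric vector of length 9.
#' @examples
#' motor_command(art = c(2, 0, 0, 0, 0, 0, 0), pressure = 0.5, voicing = 0.7)
#' @export
motor_command <- function(art = rep(0, 7), pressure = -0.25, voicing = -0.25,
                          config = vd_config()) {
  stopifnot(length(art) == 7, length(pressure) == 1, length(voicing) == 1)
  if (!all(is.finite(c(art, pressure, voicing))))
    stop("motor command entries must be finite")
  v <- c(pmin(pmax(art, config$art_range[1]), config$art_range[2]),
         pmin(pmax(c(pressure, voicing), config$pv_range[1]),
              config$pv_range[2]))
  names(v) <- c(paste0("art", 1:7), "pressure", "voicing")
  v
}

#' @rdname motor_command
#' @export
neutral_command <- function(config = vd_config()) {
  motor_command(pressure = config$pv_neutral, voicing = config$pv_neutral,
                config = config)
}

#' Two-command vocalization policy
#'
#' Flattens two 9-dim commands into the 18-dimensional policy vector: the
#' first command drives the articulators from 0 to 250 ms, the second from
#' 250 to 800 ms.
#'
#' @param m1,m2 motor commands (see [motor_command()]).
#' @param config a [vd_config()] list.
#' @return A named numeric vector of length 18.
#' @export
vocal_policy <- function(m1, m2, config = vd_config()) {
  m1 <- motor_command(m1[1:7], m1[8], m1[9], config)
  m2 <- motor_command(m2[1:7], m2[8], m2[9], config)
  v <- c(m1, m2)
  names(v) <- c(paste0(names(m1), "_1"), paste0(names(m2), "_2"))
  v
}

#' Area function of a vocal configuration
#'
#' Maps the seven articulatory positions of a command onto cross-sectional
#' areas of the tube sections (glottis to lips): `area = max(0, a0 + B art)`,
#' with a fixed positive neutral profile `a0` and a fixed 7-column basis `B`
#' whose first column implements a jaw/lip-constriction axis (the tract
#' closes for `art1 >= 1` with the other articulators neutral). The tract
#' counts as closed when any pre-floor area is non-positive.
#'
#' @param cmd a 9-dim motor command (only the first 7 entries are used).
#' @param config a [vd_config()] list.
#' @return A list of class `area_function` with elements `areas`
#'   (non-negative, length `n_sections`) and `closed` (logical).
#' @examples
#' area_function(motor_command())$closed                       # open
#' area_function(motor_command(art = c(2, 0, 0, 0, 0, 0, 0)))$closed # closed
#' @export
area_function <- function(cmd, config = vd_config()) {
  rt <- vd_runtime(config)
  cmd <- motor_command(cmd[1:7], if (length(cmd) >= 9) cmd[8] else 0,
                       if (length(cmd) >= 9) cmd[9] else 0, config)
  pre <- as.numeric(rt$a0 + rt$basis %*% cmd[1:7])
  structure(list(areas = pmax(pre, 0), closed = min(pre) <= 0),
            class = "area_function")
}

#' First two resonances of a concatenated-tube area function
#'
#' Computes the lowest two resonance frequencies (Hz) of a chain of
#' equal-length lossless tube sections, closed at the glottis and open at
#' the lips, by scanning the characteristic function for sign changes and
#' refining by bisection. For a uniform tube this reproduces the analytic
#' quarter-wavelength series c/4L, 3c/4L, ...
#'
#' @param areas numeric vector of positive section areas (glottis to lips),
#'   or an `area_function` object (must be open).
#' @param config a [vd_config()] list; `tract_length`, `c_sound` and the
#'   scan grid come from here. The section length is `tract_length /
#'   length(areas)`.
#' @return Numeric vector `c(f1, f2)` in Hz.
#' @export
tract_formants <- function(areas, config = vd_config()) {
  if (inherits(areas, "area_function")) {
    if (areas$closed) stop("closed tract has no resonances")
    areas <- areas$areas
  }
  stopifnot(all(areas > 0))
  grid <- seq(config$freq_lo, config$freq_hi, by = config$freq_step)
  f <- tube_formants_cpp(matrix(areas, nrow = 1),
                         config$tract_length / length(areas),
                         config$c_sound, grid)
  c(f1 = f[1, 1], f2 = f[1, 2])
}

# Affine map Hz -> [-1, 1], clipped.
scale_formants <- function(f1, f2, config = vd_config()) {
  r <- config$formant_scale_ranges
  c(pmin(1, pmax(-1, 2 * (f1 - r[[1]]) / (r[[2]] - r[[1]]) - 1)),
    pmin(1, pmax(-1, 2 * (f2 - r[[3]]) / (r[[4]] - r[[3]]) - 1)))
}

#' Instantaneous acoustics of a vocal configuration
#'
#' Phonation occurs iff pressure > 0, voicing > 0 and the tract is open.
#' When phonating, the first two tube resonances are scaled onto \[-1, 1\];
#' without phonation the formants are set to 0 (they are not measurable).
#'
#' @param cmd a 9-dim motor command.
#' @param config a [vd_config()] list.
#' @return A list with `phonating` (logical), `f1`, `f2` (scaled formants).
#' @examples
#' instantaneous_acoustics(motor_command(pressure = 0.5, voicing = 0.7))
#' @export
instantaneous_acoustics <- function(cmd, config = vd_config()) {
  cmd <- motor_command(cmd[1:7], cmd[8], cmd[9], config)
  af <- area_function(cmd, config)
  phon <- cmd[["pressure"]] > 0 && cmd[["voicing"]] > 0 && !af$closed
  if (!phon) return(list(phonating = FALSE, f1 = 0, f2 = 0))
  f <- tract_formants(af$areas, config)
  fs <- scale_formants(f[1], f[2], config)
  list(phonating = TRUE, f1 = unname(fs[1]), f2 = unname(fs[2]))
}
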