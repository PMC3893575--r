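#' Perceive a vocalization as a 6-dimensional auditory outcome
#'
#' Averages the instantaneous auditory parameters over two perception
#' windows (defaults 250--400 ms and 650--800 ms): the phonation level `I`
#' is the fraction of window samples that phonate, and the formant entries
#' are window means of the scaled formants with silent samples contributing
#' 0. Independent Gaussian observation noise (sd `noise_sd`) is then added
#' to all six entries, realizing `s = f(m) + eps`.
#'
#' @param traj a `voc_trajectory` from [vocalization_trajectory()].
#' @param config a [vd_config()] list.
#' @param noise_sd observation noise standard deviation; set 0 for the
#'   noise-free outcome.
#' @return Named numeric vector `c(i1, i2, f1_1, f1_2, f2_1, f2_2)`, with
#'   the pre-noise outcome in attribute `"prenoise"`.
#' @examples
#' traj <- vocalization_trajectory(rep(0, 18))
#' perceive(traj, noise_sd = 0) # silent: all zeros
#' @export
perceive <- function(traj, config = vd_config(), noise_sd = config$noise_sd) {
  stopifnot(inherits(traj, "voc_trajectory"))
  times <- traj$times
  if (max(times) < config$window_2[2] - 1e-9)
    stop("trajectory does not cover the perception windows")
  i1 <- which(times >= config$window_1[1] - 1e-9 &
                times <= config$window_1[2] + 1e-9)
  i2 <- which(times >= config$window_2[1] - 1e-9 &
                times <= config$window_2[2] + 1e-9)
  if (!length(i1) || !length(i2)) stop("a perception window has no samples")

  idx <- c(i1, i2)
  st <- traj$states[idx, , drop = FALSE]
  rt <- vd_runtime(config)
  pre_areas <- matrix(rt$a0, nrow(st), rt$K, byrow = TRUE) +
    st[, 1:7, drop = FALSE] %*% t(rt$basis)
  open <- apply(pre_areas, 1, min) > 0
  phon <- st[, 8] > 0 & st[, 9] > 0 & open
  f1s <- f2s <- numeric(nrow(st))
  if (any(phon)) {
    f <- tube_formants_cpp(pmax(pre_areas[phon, , drop = FALSE], 0),
                           rt$sec_len, rt$c_sound, rt$grid)
    r <- rt$formant_ranges
    f1s[phon] <- pmin(1, pmax(-1, 2 * (f[, 1] - r[1]) / (r[2] - r[1]) - 1))
    f2s[phon] <- pmin(1, pmax(-1, 2 * (f[, 2] - r[3]) / (r[4] - r[3]) - 1))
  }
  w <- rep(1:2, c(length(i1), length(i2)))
  pre <- c(tapply(as.numeric(phon), w, mean),
           tapply(f1s, w, mean), tapply(f2s, w, mean))
  pre <- as.numeric(pre)
  s <- pre + if (noise_sd > 0) rnorm(6, sd = noise_sd) else 0
  names(s) <- c("i1", "i2", "f1_1", "f1_2", "f2_1", "f2_2")
  attr(s, "prenoise") <- setNames(pre, names(s))
  s
}

#' Phone type of a window phonation level
#'
#' Vowel-like (`V`) above the vowel threshold (default `I > 0.9`), none
#' (`N`) below the silence threshold (`I < 0.1`), consonant-like (`C`) in
#' between; boundary values fall in `C` (the thresholds are strict).
#'
#' @param i numeric vector of window phonation levels.
#' @param config a [vd_config()] list.
#' @return Character vector in `c("V", "N", "C")`.
#' @examples
#' phone_type(c(0.95, 0.05, 0.5))
#' @export
phone_type <- function(i, config = vd_config()) {
  stopifnot(all(is.finite(i)))
  ifelse(i > config$v_threshold, "V",
         ifelse(i < config$n_threshold, "N", "C"))
}

#' Classify auditory outcomes into vocalization types and classes
#'
#' A vocalization's type is the ordered pair of its two window phone types
#' (9 types: VV, VN, VC, NV, NN, NC, CV, CN, CC). Types are grouped into 3
#' classes: `no_phonation` (NN only), `unarticulated` (VN, NV, CN, NC: one
#' window silent) and `articulated` (VV, VC, CV, CC: phonation in both
#' windows). Phonation levels are clipped to \[0, 1\] before thresholding so
#' that noisy outcomes classify cleanly.
#'
#' @param s a 6-dim outcome vector, or a matrix with outcomes in rows.
#' @param config a [vd_config()] list.
#' @return A data.frame with character columns `type` and `class`.
#' @examples
#' classify_outcome(c(1, 0, 0.3, 0, 0.2, 0)) # VN, unarticulated
#' @export
classify_outcome <- function(s, config = vd_config()) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  stopifnot(ncol(s) == 6)
  p1 <- phone_type(pmin(1, pmax(0, s[, 1])), config)
  p2 <- phone_type(pmin(1, pmax(0, s[, 2])), config)
  type <- paste0(p1, p2)
  data.frame(type = type, class = class_of_type(type),
             stringsAsFactors = FALSE)
}

#' @rdname classify_outcome
#' @param type character vector of vocalization types (e.g. `"VN"`).
#' @export
class_of_type <- function(type) {
  cls <- c(NN = "no_phonation",
           VN = "unarticulated", NV = "unarticulated",
           CN = "unarticulated", NC = "unarticulated",
           VV = "articulated", VC = "articulated",
           CV = "articulated", CC = "articulated")
  out <- unname(cls[type])
  if (anyNA(out)) stop("unknown vocalization type")
  out
}

# Canonical orderings used by the analysis tables.
voc_types <- c("NN", "CN", "NC", "VN", "NV", "VV", "CV", "VC", "CC")
voc_classes <- c("no_phonation", "unarticulated", "articulated")
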