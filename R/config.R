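#' Simulator configuration
#'
#' Returns the full list of tunable parameters with their defaults. Any
#' parameter can be overridden by name. The defaults define the reference
#' study conditions: a 20-section surrogate vocal tract, 800 ms vocalizations
#' with a command switch at 250 ms, perception windows 250--400 ms and
#' 650--800 ms, observation noise sd 0.01, a 28-component sensorimotor
#' mixture updated every 400 vocalizations with a learning rate decaying
#' logarithmically from 0.1 to 0.01, and a 6-component competence-progress
#' interest mixture refit every 400 vocalizations.
#'
#' @param ... named overrides of any default value.
#'
#' @details Selected keys:
#' \describe{
#'   \item{n_sections}{number of tube sections of the area function (20).}
#'   \item{tract_length, c_sound}{vocal-tract length (m) and speed of sound
#'     (m/s) used by the lossless-tube resonance computation.}
#'   \item{formant_scale_ranges}{Hz ranges mapped affinely onto \[-1, 1\]:
#'     F1 from \[200, 1000\], F2 from \[500, 3000\] (typical adult ranges).}
#'   \item{zeta, omega0}{damping ratio (1.01, overdamped) and natural
#'     frequency of the spring-mass motor system; `omega0` defaults to
#'     2*pi*0.8 rad/s. The faster alternative reading 2*pi/0.8 (period equal
#'     to the vocalization duration) is also supported.}
#'   \item{pv_onset}{"command" (default): pressure and voicing are fast
#'     glottal/respiratory parameters that hold their first command value
#'     from vocalization onset, so window-1 phonation is governed by the
#'     first command; "neutral": they relax from -0.25 through the
#'     spring-mass dynamics like the articulators.}
#'   \item{dt, switch_time, duration}{trajectory resolution (s), command
#'     switch (0.25 s) and vocalization duration (0.8 s).}
#'   \item{window_1, window_2}{perception windows (s).}
#'   \item{v_threshold, n_threshold}{phone-type thresholds on the window
#'     phonation level (vowel above 0.9, none below 0.1).}
#'   \item{noise_sd}{observation noise added to the 6-dim outcome (0.01).}
#'   \item{sm_components, sm_step}{sensorimotor mixture size (28) and batch
#'     size between incremental EM updates (400).}
#'   \item{alpha_start, alpha_end, total_updates}{learning-rate schedule;
#'     `total_updates` is replaced by the planned run length / `sm_step`
#'     when a run is started, and only used as-is for open-ended runs.}
#'   \item{im_components, im_window, im_refit_every}{interest mixture size
#'     (6), history window and refit cadence (400).}
#'   \item{negligible_factor}{weight multiplier for mixture components whose
#'     time-competence covariance is non-positive (1e-6).}
#'   \item{n_init, init_sd}{initialization: number of seed vocalizations
#'     (2000) sampled around the neutral command with sd 0.3.}
#' }
#'
#' @return A named list of class `vd_config`.
#' @seealso [read_config()]
#' @examples
#' cfg <- vd_config(noise_sd = 0)
#' cfg$omega0
#' @export
vd_config <- function(...) {
  cfg <- list(
    # surrogate synthesizer
    n_sections = 20L,
    tract_length = 0.175,
    c_sound = 350,
    neutral_profile = NULL,   # NULL = built-in profile
    basis_matrix = NULL,      # NULL = built-in basis; or path to a CSV
    formant_scale_ranges = c(f1_lo = 200, f1_hi = 1000,
                             f2_lo = 500, f2_hi = 3000),
    freq_lo = 20, freq_hi = 4500, freq_step = 40,
    # motor ranges / neutral values
    art_range = c(-3, 3),
    pv_range = c(-1, 1),
    pv_neutral = -0.25,
    pv_onset = "command", # "command": glottal parameters act fast and hold
                          # their first command from vocalization onset;
                          # "neutral": they relax from -0.25 like articulators

    # dynamics
    zeta = 1.01,
    omega0 = 2 * pi * 0.8,
    dt = 0.01,
    switch_time = 0.25,
    duration = 0.8,
    # perception
    window_1 = c(0.25, 0.40),
    window_2 = c(0.65, 0.80),
    v_threshold = 0.9,
    n_threshold = 0.1,
    noise_sd = 0.01,
    # sensorimotor model
    sm_components = 28L,
    sm_step = 400L,
    alpha_start = 0.1,
    alpha_end = 0.01,
    total_updates = 600L,
    em_tol = 1e-6,
    em_max_iter = 200L,
    cov_floor = 1e-6,
    inc_sweeps = 5L,
    # interest model
    im_components = 6L,
    im_window = 2000L,
    im_refit_every = 400L,
    im_em_max_iter = 60L,
    negligible_factor = 1e-6,
    strategy_threshold = 0.5,
    # agent initialization
    n_init = 2000L,
    init_sd = 0.3,
    # analysis
    demo_delta = 0.2,
    mix_threshold = 0.25,
    min_stage = 3L,
    verbose = FALSE
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  structure(cfg, class = "vd_config")
}

#' Read a configuration file
#'
#' Loads overrides from a YAML or JSON file and merges them into the
#' defaults of [vd_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file whose top-level keys
#'   are configuration names.
#' @return A `vd_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  over <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(vd_config, as.list(over))
}

# Internal: assemble derived run-time constants (basis, dynamics roots,
# perception-window exponentials, frequency grid, clip ranges).
vd_runtime <- function(config = vd_config()) {
  K <- as.integer(config$n_sections)
  u <- (seq_len(K) - 0.5) / K # glottis (0) -> lips (1)
  a0 <- config$neutral_profile
  if (is.null(a0)) a0 <- 2.6 - 1.4 * u
  if (length(a0) != K || any(a0 <= 0))
    stop("neutral_profile must have n_sections positive entries")
  B <- config$basis_matrix
  if (is.character(B)) B <- as.matrix(utils::read.csv(B, header = FALSE))
  if (is.null(B)) B <- default_basis(u, a0)
  B <- unname(as.matrix(B))
  if (!all(dim(B) == c(K, 7L))) stop("basis_matrix must be n_sections x 7")

  zeta <- config$zeta; w0 <- config$omega0
  if (zeta <= 1) stop("zeta must exceed 1 (overdamped)")
  disc <- sqrt(zeta^2 - 1)
  r1 <- w0 * (-zeta + disc)
  r2 <- w0 * (-zeta - disc)

  times <- seq(0, config$duration, by = config$dt)
  in_win <- function(w) which(times >= w[1] - 1e-9 & times <= w[2] + 1e-9)
  i1 <- in_win(config$window_1); i2 <- in_win(config$window_2)
  if (!length(i1) || !length(i2)) stop("empty perception window")
  if (min(times[c(i1, i2)]) < config$switch_time - 1e-9)
    stop("perception windows must start at or after switch_time")
  tw <- times[c(i1, i2)] - config$switch_time

  grid <- seq(config$freq_lo, config$freq_hi, by = config$freq_step)
  x_init <- c(rep(0, 7), config$pv_neutral, config$pv_neutral)
  m_lo <- c(rep(config$art_range[1], 7), rep(config$pv_range[1], 2))
  m_hi <- c(rep(config$art_range[2], 7), rep(config$pv_range[2], 2))

  list(K = K, u = u, a0 = a0, basis = B,
       sec_len = config$tract_length / K, c_sound = config$c_sound,
       formant_ranges = unname(config$formant_scale_ranges),
       grid = grid,
       r1 = r1, r2 = r2,
       times = times, w1_idx = i1, w2_idx = i2,
       e1_w = exp(r1 * tw), e2_w = exp(r2 * tw), n_w1 = length(i1),
       x_init = x_init,
       m_lo = rep(m_lo, 2), m_hi = rep(m_hi, 2),
       goal_lo = c(0, 0, -1, -1, -1, -1),
       goal_hi = c(1, 1, 1, 1, 1, 1))
}

# Hand-designed 7-column area basis. Column 1 is the jaw/lip-constriction
# axis, scaled so that the tract closes exactly at art1 = 1 with the other
# articulators neutral; columns 2-3 are tongue-body shifts and columns 4-7
# progressively smaller local deformations.
default_basis <- function(u, a0) {
  bump <- function(c0, w) exp(-((u - c0) / w)^2)
  b1 <- -a0 * bump(max(u), 0.08) / max(bump(max(u), 0.08))
  b2 <- 0.35 * cos(pi * u)
  b3 <- -0.35 * bump(0.45, 0.18)
  b4 <- 0.25 * sin(2 * pi * u)
  b5 <- -0.20 * bump(0.20, 0.10)
  b6 <- 0.15 * sin(3 * pi * u)
  b7 <- -0.10 * bump(0.60, 0.08)
  cbind(b1, b2, b3, b4, b5, b6, b7, deparse.level = 0)
}
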