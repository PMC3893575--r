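#' Closed-form segment of the overdamped spring-mass motor system
#'
#' Each motor dimension follows `x'' + 2*zeta*omega0*x' + omega0^2 (x - m) =
#' 0` toward its command value `m`. With zeta > 1 the closed-form solution is
#' `x(t) = m + A exp(r1 t) + B exp(r2 t)` with `r1,2 = omega0 (-zeta +/-
#' sqrt(zeta^2 - 1))` and A, B fixed by the initial state; the motion never
#' overshoots.
#'
#' @param x0,v0 initial state and velocity (any common length).
#' @param m command values (same length).
#' @param duration segment duration in seconds (> 0).
#' @param dt time step in seconds (> 0).
#' @param zeta damping ratio (> 1).
#' @param omega0 natural frequency (rad/s).
#' @return A list with `times` (from 0), `states` and `velocities`
#'   (matrices, time in rows).
#' @examples
#' seg <- solve_segment(0, 0, 1, duration = 0.25, dt = 0.01)
#' tail(seg$states, 1) # approaches 1 without overshoot
#' @export
solve_segment <- function(x0, v0, m, duration, dt,
                          zeta = 1.01, omega0 = 2 * pi * 0.8) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  stopifnot(length(x0) == length(v0), length(x0) == length(m), zeta > 1)
  disc <- sqrt(zeta^2 - 1)
  r1 <- omega0 * (-zeta + disc)
  r2 <- omega0 * (-zeta - disc)
  D <- x0 - m
  A <- (v0 - r2 * D) / (r1 - r2)
  B <- D - A
  times <- seq(0, duration, by = dt)
  E1 <- exp(r1 * times); E2 <- exp(r2 * times)
  states <- outer(E1, A) + outer(E2, B) +
    matrix(m, length(times), length(m), byrow = TRUE)
  velocities <- outer(r1 * E1, A) + outer(r2 * E2, B)
  list(times = times, states = states, velocities = velocities)
}

#' Articulatory trajectory of a two-command vocalization
#'
#' Evaluates the overdamped spring-mass dynamics over the full vocalization:
#' segment 1 starts at rest with the articulators in the neutral position 0
#' and is driven by the first command until `switch_time` (250 ms); segment
#' 2 continues from the exact segment-1 end state toward the second command
#' until `duration` (800 ms). Pressure and voicing either hold their first
#' command value from onset (`pv_onset = "command"`, the default: glottal
#' parameters act fast) or start from their -0.25 resting value like the
#' articulators (`pv_onset = "neutral"`).
#' State and velocity are continuous across the switch by construction, and
#' the segment-2 endpoint depends on both commands (coarticulation).
#'
#' @param policy an 18-dim policy from [vocal_policy()] (or any numeric of
#'   length 18, clipped to range).
#' @param config a [vd_config()] list.
#' @param dt time step; defaults to `config$dt`.
#' @return A list of class `voc_trajectory` with `times`, `states`,
#'   `velocities` (9 columns: art1..7, pressure, voicing) and the clipped
#'   `policy`.
#' @export
vocalization_trajectory <- function(policy, config = vd_config(),
                                    dt = config$dt) {
  stopifnot(length(policy) == 18)
  policy <- vocal_policy(policy[1:9], policy[10:18], config)
  n_sw <- config$switch_time / dt
  if (abs(n_sw - round(n_sw)) > 1e-8)
    stop("switch_time must be a multiple of dt")
  rt <- vd_runtime(config)
  x0 <- rt$x_init
  if (identical(config$pv_onset, "command")) x0[8:9] <- policy[8:9]
  seg1 <- solve_segment(x0, rep(0, 9), policy[1:9],
                        duration = config$switch_time, dt = dt,
                        zeta = config$zeta, omega0 = config$omega0)
  nt1 <- length(seg1$times)
  seg2 <- solve_segment(seg1$states[nt1, ], seg1$velocities[nt1, ],
                        policy[10:18],
                        duration = config$duration - config$switch_time,
                        dt = dt, zeta = config$zeta, omega0 = config$omega0)
  times <- c(seg1$times, seg2$times[-1] + config$switch_time)
  states <- rbind(seg1$states, seg2$states[-1, , drop = FALSE])
  velocities <- rbind(seg1$velocities, seg2$velocities[-1, , drop = FALSE])
  colnames(states) <- colnames(velocities) <-
    c(paste0("art", 1:7), "pressure", "voicing")
  structure(list(times = times, states = states, velocities = velocities,
                 policy = policy),
            class = "voc_trajectory")
}
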