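test_that("a segment starting at its command stays there", {
  seg <- solve_segment(x0 = c(1, -2), v0 = c(0, 0), m = c(1, -2),
                       duration = 0.25, dt = 0.01)
  expect_equal(max(abs(seg$states - rep(c(1, -2), each = 26))), 0,
               tolerance = 1e-12)
})

test_that("segments reject non-positive durations and steps", {
  expect_error(solve_segment(0, 0, 1, duration = 0, dt = 0.01), "positive")
  expect_error(solve_segment(0, 0, 1, duration = 0.1, dt = -1), "positive")
})

test_that("overdamped motion never overshoots its command", {
  set.seed(7)
  for (i in 1:20) {
    x0 <- runif(1, -3, 3); m <- runif(1, -3, 3)
    seg <- solve_segment(x0, 0, m, duration = 0.8, dt = 0.005)
    expect_true(all(sign(seg$states - m) == sign(x0 - m) |
                      abs(seg$states - m) < 1e-12))
  }
})

test_that("a distant command is undershot at 250 ms but approached by 800 ms", {
  # both commands at 2.0 from rest: not reached at the switch, nearly
  # reached by the end of the vocalization
  pol <- vocal_policy(c(0, 0, 2, 0, 0, 0, 0, 0.5, 0.7),
                      c(0, 0, 2, 0, 0, 0, 0, 0.5, 0.7))
  traj <- vocalization_trajectory(pol)
  x25 <- traj$states[traj$times == 0.25, "art3"]
  x80 <- traj$states[traj$times == 0.80, "art3"]
  expect_lt(x25, 2)
  expect_lt(abs(x80 - 2), abs(x25 - 2))
})

test_that("a reversed command is undershot after a strong first command", {
  pol <- vocal_policy(c(2, rep(0, 6), 0.5, 0.7),
                      c(-3, rep(0, 6), 0.5, 0.7))
  traj <- vocalization_trajectory(pol)
  x25 <- traj$states[traj$times == 0.25, "art1"]
  x80 <- traj$states[traj$times == 0.80, "art1"]
  expect_gt(x80, -3)   # -3 not reached
  expect_lt(x80, x25)  # but moving toward it
})

test_that("state and velocity are continuous across the command switch", {
  set.seed(11)
  for (i in 1:5) {
    pol <- c(runif(7, -3, 3), runif(2, -1, 1),
             runif(7, -3, 3), runif(2, -1, 1))
    cfg <- vd_config(dt = 0.005)
    traj <- vocalization_trajectory(pol, cfg)
    x0 <- vocadev:::vd_runtime(cfg)$x_init
    x0[8:9] <- pol[8:9] # glottal parameters start at their first command
    seg1 <- solve_segment(x0, rep(0, 9), pol[1:9], 0.25, 0.005)
    i25 <- which(abs(traj$times - 0.25) < 1e-9)
    expect_lt(max(abs(traj$states[i25, ] - seg1$states[51, ])), 1e-9)
    expect_lt(max(abs(traj$velocities[i25, ] - seg1$velocities[51, ])),
              1e-9)
  }
})

test_that("the segment-2 endpoint depends on the first command (coarticulation)", {
  m2 <- c(rep(0.5, 7), 0.5, 0.5)
  t_a <- vocalization_trajectory(vocal_policy(rep(0, 9) * c(rep(1, 7), 0, 0) +
                                                c(rep(0, 7), -0.25, -0.25),
                                              m2))
  t_b <- vocalization_trajectory(vocal_policy(c(rep(2, 7), -0.25, -0.25),
                                              m2))
  end_a <- t_a$states[nrow(t_a$states), ]
  end_b <- t_b$states[nrow(t_b$states), ]
  expect_gt(max(abs(end_a - end_b)), 1e-3)
})

test_that("closed form matches an independent ODE integrator", {
  skip_if_not_installed("deSolve")
  cfg <- vd_config()
  ode_segment <- function(x0, v0, m, tt, zeta, w0) {
    deriv <- function(t, y, p)
      list(c(y[2], -2 * zeta * w0 * y[2] - w0^2 * (y[1] - m)))
    deSolve::ode(c(x0, v0), tt, deriv, NULL, method = "rk4",
                 hini = 1e-5)[, 2]
  }
  set.seed(3)
  for (i in 1:10) {
    x0 <- runif(1, -3, 3); v0 <- runif(1, -5, 5); m <- runif(1, -3, 3)
    tt <- seq(0, 0.25, by = 0.05)
    seg <- solve_segment(x0, v0, m, 0.25, 0.05, cfg$zeta, cfg$omega0)
    expect_equal(seg$states[, 1],
                 ode_segment(x0, v0, m, tt, cfg$zeta, cfg$omega0),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})
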