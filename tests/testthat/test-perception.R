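test_that("a silent trajectory is perceived as the zero outcome", {
  traj <- vocalization_trajectory(rep(neutral_command(), 2))
  s <- perceive(traj, noise_sd = 0)
  expect_equal(unname(s), rep(0, 6), ignore_attr = TRUE)
})

test_that("window means recover constant phonation and formants", {
  # hold a phonating configuration from the start: both windows fully
  # phonating with the same formants
  cmd <- motor_command(rep(0, 7), 0.8, 0.8)
  pol <- vocal_policy(cmd, cmd)
  s <- perceive(vocalization_trajectory(pol), noise_sd = 0)
  ia <- instantaneous_acoustics(cmd)
  expect_equal(unname(s[1:2]), c(1, 1))
  expect_equal(unname(s[3:4]), rep(ia$f1, 2), tolerance = 1e-6)
  expect_equal(unname(s[5:6]), rep(ia$f2, 2), tolerance = 1e-6)
})

test_that("a vowel-then-silence policy is perceived as VN", {
  pol <- vocal_policy(motor_command(rep(0, 7), 1, 1),
                      motor_command(rep(0, 7), -1, -1))
  s <- perceive(vocalization_trajectory(pol), noise_sd = 0)
  expect_gt(s[["i1"]], 0.9)
  expect_lt(s[["i2"]], 0.1)
  expect_equal(unname(s[c("f1_2", "f2_2")]), c(0, 0), tolerance = 0.05)
  cl <- classify_outcome(s)
  expect_equal(cl$type, "VN")
  expect_equal(cl$class, "unarticulated")
})

test_that("phone types follow the strict thresholds", {
  expect_equal(phone_type(c(0.95, 0.05, 0.5)), c("V", "N", "C"))
  # boundary values are consonant-like (open boundaries)
  expect_equal(phone_type(c(0.9, 0.1)), c("C", "C"))
})

test_that("the 9 types partition into the 3 classes", {
  types <- as.vector(outer(c("V", "N", "C"), c("V", "N", "C"), paste0))
  cls <- class_of_type(types)
  expect_setequal(types[cls == "no_phonation"], "NN")
  expect_setequal(types[cls == "unarticulated"], c("VN", "NV", "CN", "NC"))
  expect_setequal(types[cls == "articulated"], c("VV", "VC", "CV", "CC"))
  expect_error(class_of_type("XX"), "unknown")

  expect_equal(classify_outcome(c(1, 0, .3, 0, .2, 0))$type, "VN")
  expect_equal(classify_outcome(rep(0, 6))$class, "no_phonation")
  expect_equal(classify_outcome(c(.96, .98, .1, -.2, .3, .4))$type, "VV")
  expect_equal(classify_outcome(c(.96, .98, .1, -.2, .3, .4))$class,
               "articulated")
})

test_that("classes span outcome subspaces of increasing dimensionality", {
  set.seed(5)
  n <- 600
  M <- matrix(runif(n * 18, -1.5, 1.5), n, 18)
  M[, c(8, 9, 17, 18)] <- runif(n * 4, -1, 1)
  ex <- execute_policies(M, vd_config(), noise_sd = 0)
  cl <- classify_outcome(ex$s)$class
  s <- ex$s
  # no-phonation outcomes concentrate at the origin (both windows have
  # intensity below 0.1, so every coordinate is below the N threshold)
  np <- s[cl == "no_phonation", , drop = FALSE]
  if (nrow(np)) expect_lt(max(abs(np)), 0.1)
  un <- s[cl == "unarticulated", , drop = FALSE]
  if (nrow(un) > 1) {
    # one window's (i, f1, f2) triple is near zero in every row
    w1 <- abs(un[, c(1, 3, 5)]); w2 <- abs(un[, c(2, 4, 6)])
    expect_true(all(pmin(apply(w1, 1, max), apply(w2, 1, max)) < 0.1 + 1e-9))
  }
  ar <- s[cl == "articulated", , drop = FALSE]
  if (nrow(ar) > 5) expect_true(all(apply(ar, 2, sd) > 0))
})

test_that("observation noise has the configured standard deviation", {
  traj <- vocalization_trajectory(
    vocal_policy(motor_command(rep(0, 7), 0.8, 0.8),
                 motor_command(rep(0, 7), 0.8, 0.8)))
  set.seed(8)
  S <- t(replicate(1000, perceive(traj, noise_sd = 0.01)))
  sds <- apply(S, 2, sd)
  expect_true(all(sds > 0.008 & sds < 0.012))
})

test_that("a trajectory not covering the windows is rejected", {
  traj <- vocalization_trajectory(rep(0, 18))
  traj$times <- traj$times[traj$times <= 0.5]
  traj$states <- traj$states[seq_along(traj$times), ]
  expect_error(perceive(traj), "windows")
})
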