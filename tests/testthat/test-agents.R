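cfg_small <- vd_config(n_init = 300)

test_that("initialization is mostly non-phonatory and deterministic", {
  ag1 <- initialize_agent(2000, vd_config(), seed = 21)
  cl <- classify_outcome(ag1$s_init)$class
  expect_gte(mean(cl == "no_phonation"), 0.8)
  ag2 <- initialize_agent(2000, vd_config(), seed = 21)
  expect_identical(ag1$m_init, ag2$m_init)
  expect_identical(ag1$gsm$means, ag2$gsm$means)
  expect_identical(ag1$gim$mixture$means, ag2$gim$mixture$means)
  expect_error(initialize_agent(50, vd_config()), "at least")
})

test_that("a zero-length run keeps only the initialization records", {
  run <- run_sagg_riac(0, cfg_small, seed = 2)
  expect_equal(run$n, 0)
  expect_equal(nrow(run$m), 0)
  expect_equal(nrow(run$m_init), 300)
  expect_equal(nrow(as.data.frame(run)), 0)
})

test_that("runs are reproducible and internally consistent", {
  r1 <- run_sagg_riac(850, cfg_small, seed = 7)
  r2 <- run_sagg_riac(850, cfg_small, seed = 7)
  expect_identical(r1$m, r2$m)
  expect_identical(r1$s, r2$s)
  expect_identical(r1$competence, r2$competence)
  # conservation: stored competence matches the stored vectors
  expect_equal(r1$competence,
               exp(-sqrt(rowSums((r1$s_g - r1$s)^2))), tolerance = 1e-12)
  # stored classes match reclassification of the stored outcomes
  expect_identical(r1$class, classify_outcome(r1$s, cfg_small)$class)
})

test_that("goal-directed policies stay inside the motor ranges", {
  run <- run_sagg_riac(850, cfg_small, seed = 3)
  art <- run$m[, c(1:7, 10:16)]
  pv <- run$m[, c(8, 9, 17, 18)]
  expect_true(all(art >= -3 & art <= 3))
  expect_true(all(pv >= -1 & pv <= 1))
})

test_that("packaged teachers produce valid, distinct demonstration sets", {
  for (id in 1:3) {
    te <- teacher(id)
    expect_equal(nrow(te$demos), 2)
    expect_true(all(te$demos[, 2] > 0.9))   # vowel-like second phone
    expect_true(all(te$demos[, 1] < 0.5))   # low first-window intensity
  }
  # noise-free construction is deterministic
  expect_identical(teacher(1)$demos, teacher(1)$demos)
  sep <- sqrt(sum((teacher(2)$demos[, 3:6] - teacher(3)$demos[, 3:6])^2))
  expect_gte(sep, 0.3)
  # a non-phonating program is rejected
  expect_error(make_teacher(matrix(rep(neutral_command(), 2), 1)),
               "i2")
})

test_that("strategic runs record strategies and emulation goals", {
  te <- teacher(1)
  run <- run_sgim_acts(850, te, cfg_small, seed = 5)
  expect_setequal(unique(run$strategy), c(0L, 1L))
  soc <- which(run$strategy == 1)
  # social-guidance goals are exactly the teacher's demonstrations
  if (length(soc)) {
    d <- apply(run$s_g[soc, , drop = FALSE], 1,
               function(g) min(sqrt(colSums((t(te$demos) - g)^2))))
    expect_lt(max(d), 1e-9)
  }
  r2 <- run_sgim_acts(850, te, cfg_small, seed = 5)
  expect_identical(run$m, r2$m)
  expect_identical(run$strategy, r2$strategy)
})

test_that("run records survive a serialization round trip", {
  run <- run_sagg_riac(850, cfg_small, seed = 11)
  prefix <- tempfile()
  write_run(run, prefix)
  back <- read_run(prefix)
  expect_equal(back$s, run$s, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$class, run$class)
  expect_identical(back$strategy, run$strategy)
  # analyses recompute identically from the serialized record
  p1 <- windowed_class_proportions(run, window = 200)
  p2 <- windowed_class_proportions(back, window = 200)
  expect_identical(p1, p2)
  t1 <- stage_tables(run, segment_stages(p1))
  t2 <- stage_tables(back, segment_stages(p2))
  expect_identical(t1, t2)
})
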