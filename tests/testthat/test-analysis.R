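test_that("windowed proportions count classes exactly and sum to 1", {
  cls <- c(rep("NN", 50), rep("VN", 50))
  types <- cls
  labels <- class_of_type(types)
  p <- windowed_class_proportions(labels, window = 100)
  expect_equal(nrow(p), 1)
  expect_equal(p$no_phonation, 0.5)
  expect_equal(p$unarticulated, 0.5)
  expect_equal(p$articulated, 0)

  p2 <- windowed_class_proportions(rep("no_phonation", 500), window = 100,
                                   step = 50)
  expect_true(all(p2$no_phonation == 1))
  set.seed(1)
  mixed <- sample(c("no_phonation", "unarticulated", "articulated"), 1000,
                  TRUE)
  p3 <- windowed_class_proportions(mixed, window = 300, step = 100)
  expect_equal(rowSums(p3[, 3:5]), rep(1, nrow(p3)), tolerance = 1e-9)
})

test_that("stage segmentation recovers clean label blocks", {
  cls <- c(rep("no_phonation", 300), rep("unarticulated", 300),
           rep("articulated", 300))
  p <- windowed_class_proportions(cls, window = 50, step = 25)
  seg <- segment_stages(p, min_stage = 2)
  expect_equal(seg$label, c("no_phonation_unarticulated", "unarticulated",
                            "articulated"))
  expect_equal(seg$from[1], 1)
  expect_equal(seg$to[3], 900)
  expect_true(all(seg$from[-1] == head(seg$to, -1) + 1))

  seg1 <- segment_stages(windowed_class_proportions(
    rep("articulated", 400), window = 100))
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$label, "articulated")
})

test_that("short spurious runs are merged into their neighbours", {
  cls <- c(rep("no_phonation", 300), rep("unarticulated", 20),
           rep("no_phonation", 300), rep("articulated", 400))
  p <- windowed_class_proportions(cls, window = 40, step = 40)
  seg <- segment_stages(p, min_stage = 3)
  expect_equal(seg$label,
               c("no_phonation_unarticulated", "articulated"))
})

test_that("stage tables count types exactly and sum to 100", {
  types <- c("VN", "VN", "NN", "VV")
  seg <- structure(data.frame(stage = 1L, label = "unarticulated",
                              from = 1L, to = 4L),
                   class = c("vd_stages", "data.frame"))
  tb <- stage_tables(types, seg)
  expect_equal(tb[1, "VN"], 50)
  expect_equal(tb[1, "NN"], 25)
  expect_equal(tb[1, "VV"], 25)
  expect_equal(sum(tb), 100)
})

test_that("stage-sequence tables tally labels per stage index", {
  seg <- function(...) {
    labs <- c(...)
    structure(data.frame(stage = seq_along(labs), label = labs,
                         from = 1L, to = 2L),
              class = c("vd_stages", "data.frame"))
  }
  tab <- stage_sequence_table(list(
    seg("no_phonation_unarticulated", "unarticulated", "articulated"),
    seg("no_phonation_unarticulated", "unarticulated"),
    seg("unarticulated", "articulated")))
  expect_equal(tab["no_phonation_unarticulated", 1], 2L)
  expect_equal(tab["unarticulated", 2], 2L)
  expect_equal(tab["articulated", 3], 1L)
  expect_equal(tab["articulated", 2], 1L)
})

test_that("strategy curves recover alternation shares and flat progress", {
  cfg <- vd_config(sm_step = 100L)
  n <- 1000
  run <- structure(list(
    n = n, seed = 1, algo = "sgim", config = cfg, teacher = NULL,
    strategy = rep(c(0L, 1L), n / 2),
    competence = rep(0.5, n),
    s = matrix(0, n, 6), s_g = matrix(0, n, 6), m = matrix(0, n, 18),
    type = rep("NN", n), class = rep("no_phonation", n)),
    class = "voc_run")
  sc <- strategy_curves(run, window = 5)
  expect_equal(sc$usage_social, rep(0.5, 10), tolerance = 1e-9)
  expect_equal(sc$usage_autonomous, rep(0.5, 10), tolerance = 1e-9)
  late <- !is.na(sc$progress_social)
  expect_lt(max(abs(sc$progress_social[late])), 1e-9)

  # self-exploration-only: usage is identically 1 for autonomous
  run$strategy <- rep(0L, n)
  sc0 <- strategy_curves(run, window = 5)
  expect_true(all(sc0$usage_autonomous == 1))
})

test_that("outcome-cloud summaries measure demo proximity and coverage", {
  cfg <- vd_config()
  te <- teacher(1)
  n <- 40
  s <- rbind(matrix(0, n / 2, 6),
             te$demos[rep(1:2, length.out = n / 2), ])
  run <- structure(list(n = n, seed = 1, algo = "sgim", config = cfg,
                        teacher = te, strategy = rep(0L, n),
                        competence = rep(1, n), s = s,
                        s_g = s, m = matrix(0, n, 18),
                        type = rep("NN", n),
                        class = rep("no_phonation", n)),
                   class = "voc_run")
  oc <- outcome_cloud_summary(run, phase_split = n / 2)
  expect_equal(oc$mature$mean_nearest_demo, 0, tolerance = 1e-12)
  expect_equal(oc$mature$share_near_demo, 1)
  expect_gt(oc$early$mean_nearest_demo, 0.5)
  expect_equal(oc$early$volume, 0) # degenerate point cloud
})

test_that("energy distance separates distinct clouds and vanishes on equal ones", {
  set.seed(2)
  X <- matrix(rnorm(600), 300, 2)
  Y <- matrix(rnorm(600, mean = 3), 300, 2)
  expect_gt(energy_distance(X, Y), 1)
  expect_lt(energy_distance(X, X), 1e-12)
  Z <- matrix(rnorm(600), 300, 2)
  expect_lt(energy_distance(X, Z), 0.2)
})
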