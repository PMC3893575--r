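#' Windowed vocalization-class proportions
#'
#' For each window start `t`, the share of the three vocalization classes
#' among vocalizations in `[t, t + window)`. This is the developmental
#' time-series from which stages are read: at full scale the reference
#' window is 1/8 of the run.
#'
#' @param run a `voc_run`, or a character vector of class labels.
#' @param window window length in vocalizations; a window larger than the
#'   run yields a single window.
#' @param step stride between window starts (default `window / 5`).
#' @return A data.frame with `start`, `end` and one share column per class
#'   (shares sum to 1).
#' @export
windowed_class_proportions <- function(run,
                                       window = max(1L, floor(run_n(run) / 8)),
                                       step = max(1L, floor(window / 5))) {
  cls <- run_classes(run)
  n <- length(cls)
  stopifnot(window >= 1, n >= 1)
  window <- min(window, n)
  starts <- seq.int(1L, max(1L, n - window + 1L), by = step)
  out <- data.frame(start = starts, end = pmin(starts + window - 1L, n))
  f <- factor(cls, levels = voc_classes)
  shares <- t(vapply(seq_along(starts), function(i) {
    idx <- seq.int(out$start[i], out$end[i])
    tabulate(f[idx], nbins = 3) / length(idx)
  }, numeric(3)))
  colnames(shares) <- voc_classes
  cbind(out, shares)
}

run_n <- function(run) if (inherits(run, "voc_run")) run$n else length(run)
run_classes <- function(run)
  if (inherits(run, "voc_run")) run$class else as.character(run)

#' Automatic developmental-stage segmentation
#'
#' Labels each window of a class-proportion series by its dominant content
#' — `articulated` when that class has the largest share; otherwise
#' `no_phonation_unarticulated` when the no-phonation share is substantial
#' (at least `mix_threshold`, the mixed content typical of the first
#' stage), else `unarticulated` — and takes maximal contiguous runs of the
#' label as stages, merging runs shorter than `min_stage` windows into
#' their larger neighbour. Stage boundaries are placed midway between the
#' adjacent windows of different label.
#'
#' @param proportions output of [windowed_class_proportions()].
#' @param min_stage minimum stage length in windows.
#' @param mix_threshold no-phonation share above which a non-articulated
#'   window counts as the mixed first-stage content.
#' @return A data.frame of class `vd_stages` with `stage`, `label`, `from`,
#'   `to` (iteration ranges covering the run).
#' @export
segment_stages <- function(proportions, min_stage = 3L,
                           mix_threshold = 0.25) {
  p <- proportions
  stopifnot(nrow(p) >= 1)
  lab <- ifelse(
    p$articulated > pmax(p$no_phonation, p$unarticulated), "articulated",
    ifelse(p$no_phonation >= mix_threshold, "no_phonation_unarticulated",
           "unarticulated"))
  r <- rle(lab)
  # absorb short runs into their larger neighbour
  while (length(r$lengths) > 1 && min(r$lengths) < min_stage) {
    i <- which.min(r$lengths)
    nb <- if (i == 1) 2L
          else if (i == length(r$lengths)) i - 1L
          else if (r$lengths[i - 1] >= r$lengths[i + 1]) i - 1L else i + 1L
    r$values[i] <- r$values[nb]
    r <- rle(inverse.rle(r))
  }
  ends_w <- cumsum(r$lengths)
  starts_w <- c(1L, head(ends_w, -1) + 1L)
  n_iter <- max(p$end)
  from <- to <- integer(length(r$lengths))
  for (k in seq_along(r$lengths)) {
    from[k] <- if (k == 1) 1L else to[k - 1] + 1L
    to[k] <- if (k == length(r$lengths)) n_iter else
      as.integer(round((p$end[ends_w[k]] + p$start[starts_w[k] + 1L]) / 2))
  }
  structure(data.frame(stage = seq_along(r$values), label = r$values,
                       from = from, to = to),
            class = c("vd_stages", "data.frame"))
}

#' Per-stage vocalization-type percentage tables
#'
#' For each detected stage, the percentage of each of the 9 vocalization
#' types (NN, CN, NC, VN, NV, VV, CV, VC, CC) among the vocalizations
#' produced during that stage. Rows sum to 100.
#'
#' @param run a `voc_run`.
#' @param segmentation a [segment_stages()] result.
#' @return A matrix (stages x 9 types) of percentages, with stage labels as
#'   row names.
#' @export
stage_tables <- function(run, segmentation) {
  stopifnot(inherits(segmentation, "vd_stages"))
  types <- if (inherits(run, "voc_run")) run$type else as.character(run)
  out <- t(vapply(seq_len(nrow(segmentation)), function(k) {
    idx <- seq.int(segmentation$from[k], segmentation$to[k])
    100 * tabulate(factor(types[idx], levels = voc_types), nbins = 9) /
      length(idx)
  }, numeric(9)))
  dimnames(out) <- list(segmentation$label, voc_types)
  out
}

#' Cross-run stage-sequence counts
#'
#' Tabulates, over a set of independent runs, which stage label occupies
#' each stage index — the cross-seed summary of the emergent developmental
#' sequence.
#'
#' @param segmentations list of [segment_stages()] results.
#' @return A matrix (labels x stage index) of run counts.
#' @export
stage_sequence_table <- function(segmentations) {
  max_k <- max(vapply(segmentations, nrow, 0L))
  labs <- c("no_phonation_unarticulated", "unarticulated", "articulated")
  out <- matrix(0L, length(labs), max_k,
                dimnames = list(labs, paste0("stage", seq_len(max_k))))
  for (seg in segmentations)
    for (k in seq_len(nrow(seg)))
      out[seg$label[k], k] <- out[seg$label[k], k] + 1L
  out
}

#' Strategy-usage and per-strategy progress curves
#'
#' Aggregates a strategic run by sensorimotor-update blocks (`sm_step`
#' vocalizations each) and smooths over a sliding window of updates: usage
#' is the share of iterations choosing each strategy, and progress is the
#' windowed slope of the mean competence restricted to that strategy's
#' vocalizations.
#'
#' @param run a `voc_run`.
#' @param window smoothing window, in updates.
#' @return A data.frame with one row per update: `usage_autonomous`,
#'   `usage_social`, `progress_autonomous`, `progress_social`. For
#'   self-exploration-only runs the usage series is identically 1 for
#'   autonomous exploration.
#' @export
strategy_curves <- function(run, window = 100L) {
  stopifnot(inherits(run, "voc_run"), run$n > 0)
  step <- run$config$sm_step
  blk <- ceiling(seq_len(run$n) / step)
  nb <- max(blk)
  blocks <- seq_len(nb)
  mean_comp <- function(sel) {
    vapply(blocks, function(b) {
      i <- which(blk == b & sel)
      if (length(i)) mean(run$competence[i]) else NA_real_
    }, 0)
  }
  soc <- run$strategy == 1
  usage_soc <- vapply(blocks, function(b) {
    i <- which(blk %in% seq.int(max(1L, b - window + 1L), b))
    mean(soc[i])
  }, 0)
  slope <- function(series) {
    vapply(blocks, function(b) {
      i <- seq.int(max(1L, b - window + 1L), b)
      y <- series[i]
      ok <- !is.na(y)
      if (sum(ok) < 2) return(NA_real_)
      unname(coef(lm(y[ok] ~ i[ok]))[2])
    }, 0)
  }
  data.frame(update = blocks,
             usage_autonomous = 1 - usage_soc,
             usage_social = usage_soc,
             progress_autonomous = slope(mean_comp(!soc)),
             progress_social = slope(mean_comp(soc)))
}

#' Early- vs mature-phase outcome-cloud summary
#'
#' Splits a run's auditory outcomes into an early and a mature phase and
#' summarizes each cloud: 6-dim bounding box (and its volume), and, when a
#' teacher is given, the mean distance from each outcome to its nearest
#' demonstration and the share of outcomes within `delta` of any
#' demonstration.
#'
#' @param run a `voc_run`.
#' @param phase_split iteration index ending the early phase.
#' @param teacher optional `vd_teacher`.
#' @param delta demonstration-overlap radius in scaled auditory units.
#' @return A list with elements `early` and `mature`, each containing
#'   `n`, `bbox`, `volume`, and (with a teacher) `mean_nearest_demo`,
#'   `share_near_demo`.
#' @export
outcome_cloud_summary <- function(run, phase_split,
                                  teacher = run$teacher,
                                  delta = run$config$demo_delta) {
  stopifnot(inherits(run, "voc_run"), phase_split >= 1,
            phase_split < run$n)
  phase <- function(idx) {
    S <- run$s[idx, , drop = FALSE]
    bbox <- apply(S, 2, range)
    out <- list(n = length(idx), bbox = bbox,
                volume = prod(bbox[2, ] - bbox[1, ]))
    if (!is.null(teacher)) {
      d <- nearest_demo_dist(S, teacher$demos)
      out$mean_nearest_demo <- mean(d)
      out$share_near_demo <- mean(d <= delta)
    }
    out
  }
  list(early = phase(seq_len(phase_split)),
       mature = phase(seq.int(phase_split + 1L, run$n)))
}

nearest_demo_dist <- function(S, demos) {
  D <- matrix(0, nrow(S), nrow(demos))
  for (j in seq_len(nrow(demos)))
    D[, j] <- sqrt(rowSums(sweep(S, 2, demos[j, ])^2))
  apply(D, 1, min)
}

#' Energy distance between two outcome clouds
#'
#' `E = 2 E||X - Y|| - E||X - X'|| - E||Y - Y'||`, a nonnegative
#' distribution distance that is 0 iff the distributions coincide. Large
#' clouds are thinned deterministically (evenly spaced rows) before the
#' pairwise distances are computed.
#'
#' @param X,Y matrices with observations in rows.
#' @param max_n per-cloud subsample cap.
#' @return Scalar energy distance.
#' @export
energy_distance <- function(X, Y, max_n = 1000L) {
  thin <- function(M) {
    M <- as.matrix(M)
    if (nrow(M) > max_n)
      M <- M[round(seq(1, nrow(M), length.out = max_n)), , drop = FALSE]
    M
  }
  X <- thin(X); Y <- thin(Y)
  cross <- 0
  for (j in seq_len(nrow(Y)))
    cross <- cross + sum(sqrt(rowSums(sweep(X, 2, Y[j, ])^2)))
  cross <- cross / (nrow(X) * nrow(Y))
  within <- function(M) {
    if (nrow(M) < 2) return(0)
    mean(dist(M))
  }
  2 * cross - within(X) - within(Y)
}

#' Plot windowed class proportions
#'
#' Cumulative (stacked) shares of the three vocalization classes over the
#' run, the standard view in which the developmental stages appear.
#'
#' @param proportions output of [windowed_class_proportions()].
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `proportions`.
#' @export
plot_class_proportions <- function(proportions, ...) {
  p <- proportions
  x <- (p$start + p$end) / 2
  y1 <- p$no_phonation
  y2 <- y1 + p$unarticulated
  graphics::plot(x, rep(1, length(x)), type = "n", ylim = c(0, 1),
                 xlab = "vocalization", ylab = "class share", ...)
  graphics::polygon(c(x, rev(x)), c(rep(0, length(x)), rev(y1)),
                    col = "grey80", border = NA)
  graphics::polygon(c(x, rev(x)), c(y1, rev(y2)), col = "grey55",
                    border = NA)
  graphics::polygon(c(x, rev(x)), c(y2, rep(1, length(x))), col = "grey30",
                    border = NA)
  graphics::legend("topright", c("no phonation", "unarticulated",
                                 "articulated"),
                   fill = c("grey80", "grey55", "grey30"), bg = "white")
  invisible(proportions)
}
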