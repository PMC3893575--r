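#' Competence of a goal-directed vocalization
#'
#' `c = exp(-||s_g - s||)`: in (0, 1], increasing toward 1 as the Euclidean
#' distance between the goal and the realized outcome tends to 0.
#'
#' @param s_g goal vector, or matrix of goals in rows.
#' @param s realized outcome(s), same shape.
#' @return Numeric vector of competences.
#' @examples
#' competence(c(1, 0), c(1, 0)) # 1
#' competence(0, 1)             # exp(-1)
#' @export
competence <- function(s_g, s) {
  if (is.null(dim(s_g))) s_g <- matrix(s_g, nrow = 1)
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  stopifnot(all(dim(s_g) == dim(s)))
  exp(-sqrt(rowSums((s_g - s)^2)))
}

#' Recent-history records for the interest model
#'
#' Bundles the per-vocalization records the interest model is fit on: time
#' indices, the goals targeted, the competences achieved, and (for
#' strategic runs) the exploration strategy used.
#'
#' @param t strictly increasing numeric/integer time indices.
#' @param goals matrix of goals, one row per record.
#' @param competence numeric vector in (0, 1].
#' @param strategy optional integer/logical vector (0 = autonomous
#'   exploration, 1 = social guidance).
#' @return A list of class `vd_history`.
#' @export
interest_history <- function(t, goals, competence, strategy = NULL) {
  goals <- as.matrix(goals)
  stopifnot(length(t) == nrow(goals), length(competence) == nrow(goals))
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  if (!is.null(strategy)) {
    stopifnot(length(strategy) == length(t))
    strategy <- as.integer(strategy)
  }
  structure(list(t = as.numeric(t), goals = goals,
                 competence = as.numeric(competence), strategy = strategy),
            class = "vd_history")
}

#' Fit the competence-progress interest model
#'
#' A Gaussian mixture is fit by classical EM on the stacked records
#' `(t, [strategy], goal, competence)`, with time rescaled to \[0, 1\] over
#' the history window and strategy (when present) encoded as a 0/1
#' coordinate. Each component's weight is then biased by its competence
#' progress, measured as the covariance between the time and competence
#' coordinates of the component: `progress_weight ~ raw_weight *
#' cov(T, C)` for components with positive covariance, while components
#' with non-positive covariance are multiplied by a negligible factor so
#' they effectively drop out. If no component shows positive progress the
#' weights fall back to uniform (exploration fallback).
#'
#' @param history a [interest_history()].
#' @param k number of mixture components.
#' @param config a [vd_config()] list (`negligible_factor`,
#'   `strategy_threshold`, EM controls, goal clip ranges).
#' @param bias apply the competence-progress bias? Disabled for the very
#'   first fit, where the interest distribution is set to the distribution
#'   of the sounds produced during initialization.
#' @param seed optional seed forwarded to [gmm_fit_em()].
#' @return A list of class `vd_interest` with the fitted `mixture`,
#'   `raw_weights`, `progress_weights`, the index layout of the interest
#'   space and the goal clip ranges.
#' @export
fit_interest <- function(history, k = vd_config()$im_components,
                         config = vd_config(), bias = TRUE, seed = NULL) {
  stopifnot(inherits(history, "vd_history"))
  n <- length(history$t)
  if (n < k) stop("need at least k history records")
  tr <- range(history$t)
  t01 <- if (diff(tr) > 0) (history$t - tr[1]) / diff(tr) else rep(0, n)
  with_strategy <- !is.null(history$strategy)
  X <- cbind(t01,
             if (with_strategy) history$strategy,
             history$goals,
             history$competence)
  g <- gmm_fit_em(X, k, seed = seed, tol = config$em_tol,
                  max_iter = if (is.null(config$im_em_max_iter))
                    config$em_max_iter else config$im_em_max_iter,
                  floor = config$cov_floor)
  d <- ncol(X)
  tc_cov <- vapply(seq_len(k), function(j) g$covariances[1, d, j], 0)
  raw <- g$weights
  fallback <- FALSE
  if (bias) {
    pos <- tc_cov > 0
    if (any(pos)) {
      # positive-progress components share the mass in proportion to
      # raw weight x progress; the rest keep only a negligible weight
      pw <- rep(config$negligible_factor / k, k)
      pw[pos] <- raw[pos] * tc_cov[pos]
      pw[pos] <- pw[pos] / sum(pw[pos]) * (1 - sum(!pos) * config$negligible_factor / k)
    } else {
      pw <- rep(1 / k, k)
      fallback <- TRUE
    }
  } else {
    pw <- raw
  }
  pw <- pw / sum(pw)
  dg <- ncol(history$goals)
  off <- if (with_strategy) 2L else 1L
  structure(list(mixture = g, raw_weights = raw, progress_weights = pw,
                 tc_cov = tc_cov, fallback = fallback,
                 with_strategy = with_strategy,
                 goal_dims = seq.int(off + 1L, off + dg),
                 strategy_dim = if (with_strategy) 2L else NULL,
                 goal_lo = interest_goal_bounds(history, config)$lo,
                 goal_hi = interest_goal_bounds(history, config)$hi,
                 strategy_threshold = config$strategy_threshold),
            class = "vd_interest")
}

# Valid goal ranges: the auditory space for 6-dim goals (I in [0,1],
# scaled formants in [-1,1]); otherwise the recent-goal bounding box.
interest_goal_bounds <- function(history, config) {
  dg <- ncol(history$goals)
  if (dg == 6L) {
    rt <- vd_runtime(config)
    list(lo = rt$goal_lo, hi = rt$goal_hi)
  } else {
    list(lo = apply(history$goals, 2, min),
         hi = apply(history$goals, 2, max))
  }
}

# Marginal sampling mixture over ([strategy], goal) with the biased weights.
interest_sampling_mixture <- function(model) {
  stopifnot(inherits(model, "vd_interest"))
  dims <- c(model$strategy_dim, model$goal_dims)
  m <- gmm_marginal(model$mixture, dims)
  vd_gmm(model$progress_weights, m$means, m$covariances)
}

#' Sample goals (and strategies) from an interest model
#'
#' Marginalizes the biased mixture onto the goal (and strategy) coordinates
#' and samples from it; the continuous strategy coordinate is thresholded
#' at 0.5 into autonomous exploration (0) vs social guidance (1); goals are
#' clipped to the valid outcome ranges.
#'
#' @param model a fitted [fit_interest()] model.
#' @param n number of draws.
#' @return A list with `goals` (`n x d` matrix) and `strategy` (integer
#'   vector, or `NULL` for non-strategic models).
#' @export
sample_goal <- function(model, n = 1L) {
  mix <- interest_sampling_mixture(model)
  X <- gmm_sample(mix, n)
  strategy <- NULL
  if (model$with_strategy) {
    strategy <- if (isTRUE(model$fallback)) {
      # no strategy shows competence progress: equal strategy probability
      as.integer(runif(n) < 0.5)
    } else {
      as.integer(X[, 1] > model$strategy_threshold)
    }
    X <- X[, -1, drop = FALSE]
  }
  goals <- pmin(pmax(X, rep(model$goal_lo, each = n)),
                rep(model$goal_hi, each = n))
  list(goals = goals, strategy = strategy)
}
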