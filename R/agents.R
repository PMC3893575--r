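#' Execute a batch of vocalization policies
#'
#' Runs each 18-dim policy (rows) through the motor dynamics, the surrogate
#' synthesizer and windowed perception, adding observation noise to the
#' outcomes. This is the forward map `s = f(m) + eps` used everywhere by
#' the exploration loops.
#'
#' @param M matrix of policies (rows of length 18); values are clipped to
#'   range.
#' @param config a [vd_config()] list.
#' @param noise_sd observation noise sd; 0 gives the deterministic outcome.
#' @return A list with `s` (noisy outcomes, `n x 6`) and `prenoise`.
#' @export
execute_policies <- function(M, config = vd_config(),
                             noise_sd = config$noise_sd) {
  M <- as.matrix(M)
  stopifnot(ncol(M) == 18)
  rt <- vd_runtime(config)
  M <- pmin(pmax(M, rep(rt$m_lo, each = nrow(M))),
            rep(rt$m_hi, each = nrow(M)))
  out <- synthesize_batch_cpp(M, rt$a0, rt$basis, rt$sec_len, rt$c_sound,
                              rt$formant_ranges, rt$grid, rt$r1, rt$r2,
                              config$switch_time, rt$e1_w, rt$e2_w, rt$n_w1,
                              rt$x_init, noise_sd,
                              identical(config$pv_onset, "command"))
  colnames(out$s) <- colnames(out$prenoise) <-
    c("i1", "i2", "f1_1", "f1_2", "f2_1", "f2_2")
  out$m <- M
  out
}

#' @rdname execute_policies
#' @param policy a single 18-dim policy.
#' @export
vocalize <- function(policy, config = vd_config(),
                     noise_sd = config$noise_sd) {
  out <- execute_policies(matrix(policy, nrow = 1), config, noise_sd)
  setNames(out$s[1, ], colnames(out$s))
}

#' Initialize the learning agent
#'
#' The agent acquires a first set of (m, s) pairs by sampling policies
#' around the neutral configuration (articulators 0, pressure/voicing
#' -0.25, so initialization vocalizations are mostly non-phonatory),
#' executing them, and fitting the 28-component joint sensorimotor mixture
#' on the pairs. The interest model is initialized on the distribution of
#' the sounds just produced (uniform competence, progress bias disabled),
#' so the agent's first goals are sounds it already produced.
#'
#' @param n_init number of initialization vocalizations; must be at least
#'   three times the larger mixture size.
#' @param config a [vd_config()] list.
#' @param seed optional integer seed (set once at the start).
#' @param with_strategy include a strategy coordinate in the interest model
#'   (strategic runs); initialization records get uniformly random strategy
#'   labels since the agent has no prior strategy preference.
#' @return A list of class `vd_agent` with `gsm`, `gim`, `m_init`, `s_init`.
#' @export
initialize_agent <- function(n_init = vd_config()$n_init,
                             config = vd_config(), seed = NULL,
                             with_strategy = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  k_min <- max(config$sm_components, config$im_components) * 3L
  if (n_init < k_min)
    stop("n_init must be at least ", k_min)
  rt <- vd_runtime(config)
  neutral <- rep(rt$x_init, 2)
  M <- matrix(rnorm(n_init * 18, mean = rep(neutral, each = n_init),
                    sd = config$init_sd), n_init, 18)
  M <- pmin(pmax(M, rep(rt$m_lo, each = n_init)),
            rep(rt$m_hi, each = n_init))
  ex <- execute_policies(M, config, config$noise_sd)
  gsm <- gmm_fit_em(cbind(ex$m, ex$s), config$sm_components,
                    tol = config$em_tol, max_iter = config$em_max_iter,
                    floor = config$cov_floor)
  iw <- n_init # initial interest = distribution of all sounds just produced
  idx <- seq_len(n_init)
  hist0 <- interest_history(
    t = idx, goals = ex$s[idx, , drop = FALSE],
    competence = rep(1, iw),
    strategy = if (with_strategy) rbinom(iw, 1, 0.5) else NULL)
  gim <- fit_interest(hist0, k = config$im_components, config = config,
                      bias = FALSE)
  structure(list(gsm = gsm, gim = gim, m_init = ex$m, s_init = ex$s,
                 config = config, with_strategy = with_strategy),
            class = "vd_agent")
}

# Conditional-inference cache for G_SM(M | s_g): per component, the
# Cholesky of the S-block, the regression matrix K = S_MS S_SS^-1, and the
# Cholesky of the (floored) conditional covariance.
build_sm_cache <- function(gsm, floor = 1e-6) {
  k <- gsm$n_components
  dM <- 18L; dS <- 6L
  mi <- seq_len(dM); si <- dM + seq_len(dS)
  lw0 <- numeric(k)
  muS <- matrix(0, dS, k); muM <- matrix(0, dM, k)
  LS <- array(0, c(dS, dS, k))
  Km <- array(0, c(dM, dS, k))
  LC <- array(0, c(dM, dM, k))
  for (j in seq_len(k)) {
    S <- gsm$covariances[, , j]
    SBB <- floor_cov(S[si, si], floor)
    L <- t(chol(SBB))
    K <- t(backsolve(t(L), forwardsolve(L, S[si, mi])))
    SC <- S[mi, mi] - K %*% S[si, mi]
    LC[, , j] <- t(chol(floor_cov(SC, floor)))
    LS[, , j] <- L
    Km[, , j] <- K
    muS[, j] <- gsm$means[j, si]
    muM[, j] <- gsm$means[j, mi]
    lw0[j] <- log(pmax(gsm$weights[j], 1e-300)) - sum(log(diag(L)))
  }
  list(lw0 = lw0, muS = muS, LS = LS, muM = muM, K = Km, LC = LC)
}

#' Run intrinsically motivated self-exploration (active goal babbling)
#'
#' The self-exploration loop: at each iteration the agent samples an
#' auditory goal from the competence-progress interest mixture, inverts its
#' sensorimotor model by Bayesian conditioning to draw a policy, executes
#' it, perceives the noisy outcome, and records the competence
#' `exp(-||s_g - s||)`. The joint sensorimotor mixture is updated by
#' incremental EM every `sm_step` (400) vocalizations with the
#' logarithmically decaying learning rate, and the interest mixture is
#' refit on the recent history at the same cadence. Numerical failures in
#' either update are caught and the previous model retained, so a run
#' never aborts mid-stream.
#'
#' @param n number of goal-directed vocalizations.
#' @param config a [vd_config()] list.
#' @param seed integer seed; identical seed and config give a bit-identical
#'   run.
#' @param agent optional pre-initialized [initialize_agent()] (its RNG
#'   draws then belong to the caller).
#' @return A `voc_run` record with per-iteration strategy, goal, policy,
#'   outcome, competence and class labels; see [as.data.frame.voc_run()].
#' @examples
#' \donttest{
#' run <- run_sagg_riac(800, vd_config(n_init = 200), seed = 1)
#' table(run$class)
#' }
#' @export
run_sagg_riac <- function(n, config = vd_config(), seed = 1L, agent = NULL) {
  run_agent(n, config, seed, teacher = NULL, agent = agent)
}

#' Run strategic exploration with emulation of ambient sounds
#'
#' Extends [run_sagg_riac()] with a strategy choice: the interest mixture
#' is learnt over (time, strategy, goal, competence), and when the sampled
#' strategy is social guidance the goal is overwritten by a uniformly
#' random auditory demonstration from the teacher's set (emulation: the
#' agent reproduces the observed outcome with its own policies). Strategy
#' usage thus follows competence progress: emulation is chosen more once it
#' starts yielding progress, and less after the demonstrations are
#' mastered.
#'
#' @inheritParams run_sagg_riac
#' @param teacher a [make_teacher()] demonstration set.
#' @return A `voc_run` record (strategy column: 0 = autonomous, 1 = social).
#' @export
run_sgim_acts <- function(n, teacher, config = vd_config(), seed = 1L,
                          agent = NULL) {
  stopifnot(inherits(teacher, "vd_teacher"))
  run_agent(n, config, seed, teacher = teacher, agent = agent)
}

run_agent <- function(n, config, seed, teacher = NULL, agent = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  with_strategy <- !is.null(teacher)
  if (is.null(agent))
    agent <- initialize_agent(config$n_init, config,
                              with_strategy = with_strategy)
  gsm <- agent$gsm
  gim <- agent$gim
  rt <- vd_runtime(config)
  demos <- if (with_strategy) teacher$demos else matrix(0, 0, 6)

  m_rec <- matrix(NA_real_, n, 18)
  sg_rec <- s_rec <- matrix(NA_real_, n, 6)
  strat_rec <- integer(n)
  cache <- build_sm_cache(gsm, config$cov_floor)
  mix <- interest_sampling_mixture(gim)
  mix_chol <- chol_cube(mix)

  total_updates <- max(1L, as.integer(ceiling(n / config$sm_step)))
  t_updates <- 0L
  done <- 0L
  while (done < n) {
    nb <- min(config$sm_step, n - done)
    out <- run_epoch_cpp(
      nb, mix$weights, t(mix$means), mix_chol, with_strategy,
      isTRUE(gim$fallback),
      config$strategy_threshold, rt$goal_lo, rt$goal_hi, demos,
      cache$lw0, cache$muS, cache$LS, cache$muM, cache$K, cache$LC,
      rt$m_lo, rt$m_hi,
      rt$a0, rt$basis, rt$sec_len, rt$c_sound, rt$formant_ranges, rt$grid,
      rt$r1, rt$r2, config$switch_time, rt$e1_w, rt$e2_w, rt$n_w1,
      rt$x_init, config$noise_sd, identical(config$pv_onset, "command"))
    idx <- done + seq_len(nb)
    m_rec[idx, ] <- out$m
    sg_rec[idx, ] <- out$s_g
    s_rec[idx, ] <- out$s
    strat_rec[idx] <- out$strategy
    done <- done + nb

    if (nb == config$sm_step) {
      alpha <- learning_rate(t_updates, total_updates,
                             config$alpha_start, config$alpha_end)
      gsm_new <- tryCatch(
        gmm_incremental_update(gsm, cbind(out$m, out$s), alpha,
                               sweeps = config$inc_sweeps,
                               floor = config$cov_floor),
        error = function(e) {
          warning("sensorimotor update failed, keeping previous model: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(gsm_new)) {
        gsm <- gsm_new
        cache <- build_sm_cache(gsm, config$cov_floor)
      }
      t_updates <- t_updates + 1L

      iw <- min(config$im_window, done)
      hidx <- seq.int(done - iw + 1L, done)
      hist <- interest_history(
        t = hidx, goals = sg_rec[hidx, , drop = FALSE],
        competence = competence(sg_rec[hidx, , drop = FALSE],
                                s_rec[hidx, , drop = FALSE]),
        strategy = if (with_strategy) strat_rec[hidx] else NULL)
      gim_new <- tryCatch(
        fit_interest(hist, k = config$im_components, config = config,
                     bias = TRUE),
        error = function(e) {
          warning("interest refit failed, keeping previous model: ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(gim_new)) {
        gim <- gim_new
        mix <- interest_sampling_mixture(gim)
        mix_chol <- chol_cube(mix)
      }
      if (isTRUE(config$verbose))
        message(sprintf("t=%d alpha=%.4f social=%.2f", done, alpha,
                        mean(strat_rec[hidx])))
    }
  }

  colnames(s_rec) <- colnames(sg_rec) <-
    c("i1", "i2", "f1_1", "f1_2", "f2_1", "f2_2")
  comp <- if (n > 0) competence(sg_rec, s_rec) else numeric(0)
  cls <- if (n > 0) classify_outcome(s_rec, config) else
    data.frame(type = character(0), class = character(0))
  structure(list(
    n = n, seed = seed, algo = if (with_strategy) "sgim" else "sagg",
    config = config, teacher = teacher,
    m_init = agent$m_init, s_init = agent$s_init,
    strategy = strat_rec, s_g = sg_rec, m = m_rec, s = s_rec,
    competence = comp, type = cls$type, class = cls$class,
    gsm = gsm, gim = gim), class = "voc_run")
}

#' @export
print.voc_run <- function(x, ...) {
  cat(sprintf("<voc_run> %s, %d vocalizations (seed %s)\n", x$algo, x$n,
              format(x$seed)))
  if (x$n > 0) {
    tb <- table(factor(x$class, levels = voc_classes))
    cat("classes:", paste(sprintf("%s %.1f%%", names(tb),
                                  100 * tb / x$n), collapse = ", "), "\n")
    if (x$algo == "sgim")
      cat(sprintf("social guidance used in %.1f%% of iterations\n",
                  100 * mean(x$strategy)))
  }
  invisible(x)
}

#' Flatten a run record to a data.frame
#'
#' @param x a `voc_run`.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return One row per goal-directed vocalization: `t`, `strategy`,
#'   goal/policy/outcome coordinates, `competence`, `type`, `class`.
#' @export
as.data.frame.voc_run <- function(x, row.names = NULL, optional = FALSE,
                                  ...) {
  if (x$n == 0)
    return(data.frame(t = integer(0)))
  df <- data.frame(t = seq_len(x$n), strategy = x$strategy)
  sg <- x$s_g; colnames(sg) <- paste0("sg_", colnames(x$s))
  m <- x$m; colnames(m) <- paste0("m", 1:18)
  s <- x$s
  cbind(df, sg, m, s,
        data.frame(competence = x$competence, type = x$type,
                   class = x$class))
}
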