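#' Goal babbling on a 1-D toy sensorimotor map
#'
#' Minimal illustration of learning and inference in the joint
#' sensorimotor mixture: a scalar motor space M is mapped to a scalar
#' sensory space S by a fixed smooth curve, observed with substantial
#' Gaussian noise. The agent repeatedly samples a sensory goal, inverts
#' its current 2-D joint mixture by conditioning to draw a motor value,
#' executes it, and refits the mixture at a fixed cadence. Early on only
#' goals near the initial data can be reached; as experiments accumulate
#' the model covers more of the space and distant goals become reachable.
#'
#' @param n total number of sensorimotor experiments (including the
#'   initialization set).
#' @param seed integer seed.
#' @param f the unknown sensorimotor map; the default scaled
#'   cubic-plus-sine covers roughly \[-10, 10\] for motor values in
#'   \[-6.5, 6.5\].
#' @param noise_sd observation noise sd.
#' @param k mixture components.
#' @param n_init initialization experiments, motor values drawn
#'   `N(0, init_sd)` (concentrated near 0, so only central goals are
#'   reachable at first).
#' @param init_sd initialization spread.
#' @param goal_range goals are drawn uniformly from this interval.
#' @param refit_every mixture refit cadence (classical EM on all data).
#' @param eval_goals goals at which control error is measured.
#' @param eval_at times at which the evaluation is run (model snapshot
#'   taken before any same-time refit).
#' @param n_eval draws per goal per evaluation; the reported error is the
#'   location error `|median(f(m draws)) - goal|` of the induced noise-free
#'   outcome distribution.
#' @return A list with `eval` (data.frame `t`, `goal`, `error`), the final
#'   mixture `gsm`, and the experiment log `m`, `s`.
#' @examples
#' \donttest{
#' toy <- toy_goal_babbling(n = 600, seed = 1, eval_at = c(300, 600))
#' subset(toy$eval, t == 600)
#' }
#' @export
toy_goal_babbling <- function(n = 1500, seed = 1,
                              f = function(m) m^3 / 25 + sin(m),
                              noise_sd = 0.5, k = 6, n_init = 50,
                              init_sd = 1, goal_range = c(-10, 10),
                              refit_every = 400,
                              eval_goals = c(-9, 0, 8),
                              eval_at = c(500, 1000, 1500),
                              n_eval = 300) {
  stopifnot(n >= n_init, n_init >= k)
  set.seed(seed)
  M <- numeric(n); S <- numeric(n)
  M[1:n_init] <- rnorm(n_init, 0, init_sd)
  S[1:n_init] <- f(M[1:n_init]) + rnorm(n_init, 0, noise_sd)
  g <- gmm_fit_em(cbind(M[1:n_init], S[1:n_init]), k)
  evals <- list()
  eval_model <- function(g, t) {
    do.call(rbind, lapply(eval_goals, function(sg) {
      cond <- gmm_condition(g, 2, sg)
      md <- gmm_sample(cond, n_eval)[, 1]
      data.frame(t = t, goal = sg, error = abs(median(f(md)) - sg))
    }))
  }
  if (n_init %in% eval_at) evals[[length(evals) + 1]] <- eval_model(g, n_init)
  for (t in seq.int(n_init + 1L, n)) {
    sg <- runif(1, goal_range[1], goal_range[2])
    m <- gmm_sample(gmm_condition(g, 2, sg), 1)[1, 1]
    M[t] <- m
    S[t] <- f(m) + rnorm(1, 0, noise_sd)
    if (t %in% eval_at) # snapshot before any same-time refit
      evals[[length(evals) + 1]] <- eval_model(g, t)
    if (t %% refit_every == 0)
      g <- tryCatch(gmm_fit_em(cbind(M[1:t], S[1:t]), k),
                    error = function(e) g)
  }
  list(eval = do.call(rbind, evals), gsm = g, m = M, s = S)
}
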