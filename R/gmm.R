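#' Gaussian mixture container
#'
#' Plain container for a finite mixture of full-covariance Gaussians, used
#' both for the 24-dimensional joint sensorimotor model and for the
#' competence-progress interest model.
#'
#' @param weights numeric vector of non-negative component weights summing
#'   to 1 (tolerance 1e-9).
#' @param means matrix of component means, one row per component.
#' @param covariances array `d x d x k` of symmetric positive-definite
#'   component covariances.
#' @return An object of class `vd_gmm` with fields `weights`, `means`,
#'   `covariances`, `dim`, `n_components`.
#' @export
vd_gmm <- function(weights, means, covariances) {
  means <- as.matrix(means)
  k <- nrow(means); d <- ncol(means)
  stopifnot(length(weights) == k, all(dim(covariances) == c(d, d, k)))
  if (any(weights < -1e-12) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  structure(list(weights = pmax(as.numeric(weights), 0), means = means,
                 covariances = covariances, dim = d, n_components = k),
            class = "vd_gmm")
}

#' @export
print.vd_gmm <- function(x, ...) {
  cat("Gaussian mixture:", x$n_components, "components in", x$dim,
      "dimensions\n")
  invisible(x)
}

# Symmetrize and floor the eigenvalues of a covariance matrix.
floor_cov <- function(S, floor) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= floor) return(S)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

# Lower-Cholesky factors of all component covariances.
chol_cube <- function(g) {
  L <- array(0, dim(g$covariances))
  for (j in seq_len(g$n_components))
    L[, , j] <- t(chol(g$covariances[, , j]))
  L
}

logsumexp_rows <- function(M) {
  mx <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  mx + log(rowSums(exp(M - mx)))
}

# k-means++ seeding: centers drawn with probability proportional to the
# squared distance to the closest center already chosen.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((X - rep(X[idx[1], ], each = n))^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums((X - rep(X[idx[j], ], each = n))^2))
    }
  }
  X[idx, , drop = FALSE]
}

#' Fit a Gaussian mixture by classical EM
#'
#' Standard expectation-maximization with k-means++ initialization, full
#' covariances, an eigenvalue floor (so rank-deficient data never crash the
#' fit) and a relative log-likelihood stopping rule.
#'
#' @param X data matrix (observations in rows); must have at least `k` rows.
#' @param k number of components.
#' @param seed optional integer; when given, the fit is run under this seed
#'   and the caller's RNG state is restored afterwards.
#' @param tol relative log-likelihood change for convergence.
#' @param max_iter maximum EM iterations.
#' @param floor eigenvalue floor applied to every covariance update.
#' @return A [vd_gmm()] with attributes `loglik` (final total
#'   log-likelihood) and `iterations`.
#' @export
gmm_fit_em <- function(X, k, seed = NULL, tol = 1e-6, max_iter = 200L,
                       floor = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < k) stop("need at least k observations")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    }, add = TRUE)
    set.seed(seed)
  }
  mu <- kmeanspp_centers(X, k)
  S0 <- floor_cov(cov(X) * (n - 1) / max(1, n), floor)
  covs <- array(S0, c(d, d, k))
  g <- vd_gmm(rep(1 / k, k), mu, covs)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ld <- gmm_comp_logdens_cpp(X, t(g$means), chol_cube(g))
    lw <- ld + matrix(log(pmax(g$weights, 1e-300)), n, k, byrow = TRUE)
    lse <- logsumexp_rows(lw)
    ll <- sum(lse)
    R <- exp(lw - lse)
    nk <- colSums(R)
    for (j in seq_len(k)) {
      if (nk[j] < 1e-10) next # empty component keeps its parameters
      mu_j <- colSums(R[, j] * X) / nk[j]
      Xc <- X - matrix(mu_j, n, ncol(X), byrow = TRUE)
      S_j <- crossprod(sqrt(R[, j]) * Xc) / nk[j]
      g$means[j, ] <- mu_j
      g$covariances[, , j] <- floor_cov(S_j, floor)
    }
    g$weights <- nk / n
    if (iter >= max_iter || abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10))
      break
    ll_old <- ll
  }
  attr(g, "loglik") <- ll
  attr(g, "iterations") <- iter
  g
}

#' Incremental EM update of a mixture from a data batch
#'
#' One online update: responsibilities of the batch points are computed
#' under the current mixture, and each component's weight, mean and
#' covariance are replaced by the convex combination `(1 - alpha) * old +
#' alpha * batch statistics`. The learning rate `alpha` sets the relative
#' weight of new data with respect to old data. A fixed number of such E/M
#' sweeps is applied per batch; components receiving negligible
#' responsibility mass keep their parameters.
#'
#' @param g a [vd_gmm()].
#' @param X batch data matrix.
#' @param alpha learning rate in \[0, 1\]; `alpha = 0` leaves the model
#'   unchanged, `alpha = 1` (single sweep, one component) replaces the
#'   parameters by the batch sample moments.
#' @param sweeps number of E/M sweeps over the batch.
#' @param floor covariance eigenvalue floor.
#' @return The updated `vd_gmm`.
#' @seealso [learning_rate()] for the decay schedule.
#' @export
gmm_incremental_update <- function(g, X, alpha, sweeps = 5L, floor = 1e-6) {
  stopifnot(inherits(g, "vd_gmm"), alpha >= 0, alpha <= 1)
  X <- as.matrix(X)
  stopifnot(ncol(X) == g$dim)
  if (alpha == 0 || nrow(X) == 0) return(g)
  n <- nrow(X); k <- g$n_components
  for (sw in seq_len(sweeps)) {
    ld <- gmm_comp_logdens_cpp(X, t(g$means), chol_cube(g))
    lw <- ld + matrix(log(pmax(g$weights, 1e-300)), n, k, byrow = TRUE)
    R <- exp(lw - logsumexp_rows(lw))
    nk <- colSums(R)
    w_new <- g$weights
    for (j in seq_len(k)) {
      if (nk[j] < 1e-10) next
      mu_b <- colSums(R[, j] * X) / nk[j]
      Xc <- sweep(X, 2, mu_b)
      S_b <- crossprod(sqrt(R[, j]) * Xc) / nk[j]
      g$means[j, ] <- (1 - alpha) * g$means[j, ] + alpha * mu_b
      g$covariances[, , j] <-
        floor_cov((1 - alpha) * g$covariances[, , j] + alpha * S_b, floor)
      w_new[j] <- (1 - alpha) * g$weights[j] + alpha * nk[j] / n
    }
    g$weights <- w_new / sum(w_new)
  }
  g
}

#' Learning-rate schedule for the incremental sensorimotor updates
#'
#' Decreases logarithmically from `start` (0.1) at the first update to
#' `end` (0.01) at the last planned update:
#' `alpha(t) = start - (start - end) * log(1 + t) / log(1 + total)`.
#'
#' @param t_updates number of updates already performed (0-based).
#' @param total_updates total planned number of updates (>= 1).
#' @param start,end schedule endpoints.
#' @return The learning rate, a scalar in `[end, start]`.
#' @examples
#' learning_rate(0, 600)   # 0.1
#' learning_rate(600, 600) # 0.01
#' @export
learning_rate <- function(t_updates, total_updates, start = 0.1, end = 0.01) {
  stopifnot(total_updates >= 1, t_updates >= 0, t_updates <= total_updates)
  start - (start - end) * log(1 + t_updates) / log(1 + total_updates)
}

#' Condition a Gaussian mixture on a subset of its variables
#'
#' Bayesian inference on the joint mixture: per component, the Gaussian
#' conditional mean and covariance are `mu_A + S_AB S_BB^-1 (v - mu_B)` and
#' `S_AA - S_AB S_BB^-1 S_BA`, and component weights are re-weighted by the
#' marginal likelihood `N(v; mu_B, S_BB)` (computed in log space so extreme
#' conditioning values never produce NaN). This is the inverse-model
#' operation `G_SM(M | s_g)`.
#'
#' @param g a [vd_gmm()].
#' @param observed_dims integer indices of the conditioned variables (a
#'   nonempty proper subset of `1:g$dim`).
#' @param observed_values numeric vector of the same length.
#' @return A `vd_gmm` over the remaining dimensions.
#' @export
gmm_condition <- function(g, observed_dims, observed_values) {
  stopifnot(inherits(g, "vd_gmm"))
  obs <- as.integer(observed_dims)
  if (!length(obs) || length(obs) >= g$dim || anyDuplicated(obs) ||
      any(obs < 1 | obs > g$dim))
    stop("observed_dims must be a nonempty proper subset of the dimensions")
  stopifnot(length(observed_values) == length(obs))
  keep <- setdiff(seq_len(g$dim), obs)
  k <- g$n_components
  dA <- length(keep)
  means <- matrix(0, k, dA)
  covs <- array(0, c(dA, dA, k))
  lw <- numeric(k)
  for (j in seq_len(k)) {
    S <- g$covariances[, , j]
    SBB <- S[obs, obs, drop = FALSE]
    L <- t(chol(SBB))
    y <- observed_values - g$means[j, obs]
    z <- forwardsolve(L, y)
    lw[j] <- log(pmax(g$weights[j], 1e-300)) - sum(log(diag(L))) -
      0.5 * sum(z^2) - 0.5 * length(obs) * log(2 * pi)
    K <- t(backsolve(t(L), forwardsolve(L, S[obs, keep, drop = FALSE])))
    means[j, ] <- g$means[j, keep] + K %*% y
    covs[, , j] <- (S[keep, keep, drop = FALSE] -
                      K %*% S[obs, keep, drop = FALSE])
    covs[, , j] <- (covs[, , j] + t(covs[, , j])) / 2
  }
  mx <- max(lw)
  w <- if (is.finite(mx)) exp(lw - mx) else rep(1, k)
  vd_gmm(w / sum(w), means, covs)
}

#' Marginal of a Gaussian mixture
#'
#' Component-wise sub-blocks of the means and covariances; weights are
#' unchanged.
#'
#' @param g a [vd_gmm()].
#' @param dims integer indices of the dimensions to keep.
#' @return A `vd_gmm` over `dims`.
#' @export
gmm_marginal <- function(g, dims) {
  stopifnot(inherits(g, "vd_gmm"), all(dims %in% seq_len(g$dim)))
  vd_gmm(g$weights, g$means[, dims, drop = FALSE],
         g$covariances[dims, dims, , drop = FALSE])
}

#' Sample from a Gaussian mixture
#'
#' Components are chosen by weight, then a multivariate normal draw is made
#' from the chosen component.
#'
#' @param g a [vd_gmm()].
#' @param n number of draws.
#' @return An `n x dim` matrix.
#' @export
gmm_sample <- function(g, n = 1L) {
  stopifnot(inherits(g, "vd_gmm"))
  comp <- sample.int(g$n_components, n, replace = TRUE, prob = g$weights)
  Z <- matrix(rnorm(n * g$dim), n, g$dim)
  out <- matrix(0, n, g$dim)
  for (j in unique(comp)) {
    idx <- which(comp == j)
    L <- t(chol(g$covariances[, , j]))
    out[idx, ] <- rep(g$means[j, ], each = length(idx)) +
      Z[idx, , drop = FALSE] %*% t(L)
  }
  out
}

#' Mixture density and log-likelihood
#'
#' @param g a [vd_gmm()].
#' @param X data matrix (observations in rows) or a vector for a single
#'   point.
#' @return `gmm_density`: the mixture density at each row; `gmm_loglik`:
#'   the total log-likelihood.
#' @export
gmm_density <- function(g, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = g$dim)
  ld <- gmm_comp_logdens_cpp(as.matrix(X), t(g$means), chol_cube(g))
  lw <- sweep(ld, 2, log(pmax(g$weights, 1e-300)), "+")
  exp(logsumexp_rows(lw))
}

#' @rdname gmm_density
#' @export
gmm_loglik <- function(g, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = g$dim)
  ld <- gmm_comp_logdens_cpp(as.matrix(X), t(g$means), chol_cube(g))
  lw <- sweep(ld, 2, log(pmax(g$weights, 1e-300)), "+")
  sum(logsumexp_rows(lw))
}

#' Serialize a Gaussian mixture to JSON
#'
#' Writes (or returns) a documented JSON container with fields `dim`,
#' `n_components`, `weights`, `means` (row per component) and `covariances`
#' (list of matrices), readable by [gmm_from_json()].
#'
#' @param g a [vd_gmm()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
gmm_to_json <- function(g, path = NULL) {
  stopifnot(inherits(g, "vd_gmm"))
  obj <- list(container = "vd_gmm", version = 1L, dim = g$dim,
              n_components = g$n_components, weights = g$weights,
              means = apply(g$means, 1, identity, simplify = FALSE),
              covariances = lapply(seq_len(g$n_components), function(j)
                g$covariances[, , j]))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname gmm_to_json
#' @param json a JSON string or file path produced by [gmm_to_json()].
#' @export
gmm_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  if (!identical(obj$container, "vd_gmm")) stop("not a vd_gmm container")
  k <- obj$n_components; d <- obj$dim
  covs <- array(0, c(d, d, k))
  oc <- obj$covariances
  for (j in seq_len(k))
    covs[, , j] <- if (is.array(oc) && length(dim(oc)) == 3)
      oc[j, , ] else matrix(unlist(oc[[j]]), d, d)
  mm <- obj$means
  means <- if (is.list(mm)) do.call(rbind, mm) else as.matrix(mm)
  vd_gmm(obj$weights, matrix(as.numeric(means), k, d), covs)
}
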