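# Marginal maximum likelihood estimation of the Rasch model with a normal
# ability distribution (mean 0, free standard deviation), by an EM
# algorithm over a Gauss-Hermite quadrature grid.  Because the raw score is
# sufficient for ability under unit slopes, the E-step posterior over
# quadrature nodes depends on a person only through the raw score, and the
# whole EM cycle works on score-collapsed counts.

gh_rule <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))  # for integrals against N(0,1)
}

#' Fit the Rasch model by marginal maximum likelihood
#'
#' Maximizes the marginal likelihood with item slopes fixed at 1, ability
#' mean fixed at 0 and a free ability standard deviation, so the model has
#' `q = n + 1` free parameters — the parameterization under which the M2
#' test of an n-item Rasch model has `s - q` degrees of freedom.  EM cycles
#' alternate the quadrature E-step with exact M-steps (per-item Newton for
#' the difficulties, closed form for the latent variance) and stop when the
#' largest parameter change falls below `tol`.
#'
#' @param X 0/1 response matrix; every item column must be non-constant.
#' @param nodes number of Gauss-Hermite quadrature nodes.
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change per cycle.
#' @param max_cycles EM cycle cap.
#' @return An object of class `rasch_mml` with components `beta_hat`,
#'   `latent_sd`, `marg_loglik`, `q`, `converged`, `cycles`, `ll_trace`
#'   (marginal log-likelihood per cycle), `nodes`, `N`.
#' @export
rasch_mml <- function(X, nodes = 61L, tol = 1e-5, max_cycles = 500L) {
  X <- as_response_matrix(X)
  n <- ncol(X)
  N <- nrow(X)
  cs <- colSums(X)
  const <- which(cs == 0L | cs == N)
  if (length(const))
    stop_degenerate(
      paste0("constant item column(s): ",
             paste(colnames(X)[const], collapse = ", ")),
      items = const
    )
  gh <- gh_rule(nodes)
  r <- rowSums(X)
  cnt <- tabulate(r + 1L, nbins = n + 1L)          # scores 0..n
  S <- matrix(0, n, n + 1L)                        # item correct by score
  agg <- rowsum(X, group = r)
  S[, as.integer(rownames(agg)) + 1L] <- t(agg)
  marg_ll <- function(beta, sigma) {
    theta <- sigma * gh$z
    eta <- outer(theta, beta, "-")                 # K x n
    sumlogQ <- rowSums(plogis(-eta, log.p = TRUE))
    L <- outer(0:n, theta) + rep(sumlogQ, each = n + 1L) +
      rep(log(gh$w), each = n + 1L)
    A <- apply(L, 1L, function(v) { m <- max(v); m + log(sum(exp(v - m))) })
    list(ll = -sum(cs * beta) + sum(cnt * A), L = L, A = A, theta = theta)
  }
  pbar <- pmin(pmax(cs / N, 1 / (2 * N)), 1 - 1 / (2 * N))
  beta <- -qlogis(pbar)
  sigma <- 1
  ll_trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    e <- marg_ll(beta, sigma)
    ll_trace <- c(ll_trace, e$ll)
    post <- exp(e$L - e$A)                         # (n+1) x K, rows normalized
    Tk <- drop(crossprod(post, cnt))               # expected persons per node
    Rk <- S %*% post                               # n x K expected correct
    stopifnot(all(abs(rowSums(Rk) - cs) < 1e-6 * max(1, N)))
    # M-step for beta: solve sum_k Tk P_ik = cs_i per item (Newton, concave)
    beta_new <- beta
    for (it in 1:50) {
      P <- plogis(outer(e$theta, beta_new, "-"))
      f <- cs - drop(crossprod(P, Tk))
      if (max(abs(f)) < 1e-9 * max(1, N)) break
      fp <- drop(crossprod(P * (1 - P), Tk))
      beta_new <- beta_new - f / fp
    }
    sigma_new <- sqrt(sum(cnt * drop(post %*% e$theta^2)) / N)
    delta <- max(abs(beta_new - beta), abs(sigma_new - sigma))
    beta <- beta_new
    sigma <- sigma_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop_nonconvergence(
      sprintf("EM did not converge within %d cycles", max_cycles),
      last = list(beta = beta, sigma = sigma, ll_trace = ll_trace)
    )
  final <- marg_ll(beta, sigma)
  structure(
    list(beta_hat = stats::setNames(beta, colnames(X)),
         latent_sd = sigma,
         marg_loglik = final$ll,
         q = n + 1L,
         converged = TRUE,
         cycles = cycles,
         ll_trace = c(ll_trace, final$ll),
         nodes = nodes,
         gh = gh,
         N = N,
         score_counts = stats::setNames(cnt, 0:n),
         call = match.call()),
    class = "rasch_mml"
  )
}

#' @export
print.rasch_mml <- function(x, digits = 4, ...) {
  cat("Rasch model, marginal maximum likelihood (normal ability)\n")
  cat(sprintf("  persons: %d, items: %d, free parameters: %d\n",
              x$N, length(x$beta_hat), x$q))
  cat(sprintf("  latent sd: %.*f   marginal log-likelihood: %.*f\n",
              digits, x$latent_sd, digits, x$marg_loglik))
  cat(sprintf("  EM cycles: %d\n", x$cycles))
  cat("  item difficulties:\n")
  print(round(x$beta_hat, digits))
  invisible(x)
}

#' @export
coef.rasch_mml <- function(object, ...) {
  c(object$beta_hat, latent_sd = object$latent_sd)
}

#' @export
logLik.rasch_mml <- function(object, ...) {
  structure(object$marg_loglik, df = object$q, nobs = object$N,
            class = "logLik")
}

#' @export
summary.rasch_mml <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
fitted.rasch_mml <- function(object, ...) {
  model_moments(object, order = 1L)$pi1
}

#' Simulate response matrices from a fitted MML Rasch model
#'
#' @param object a [rasch_mml()] fit.
#' @param nsim number of matrices.
#' @param seed optional integer seed.
#' @param N persons per matrix (defaults to the fitted sample size).
#' @param ... unused.
#' @return A list of `nsim` response matrices.
#' @export
simulate.rasch_mml <- function(object, nsim = 1, seed = NULL, N = object$N,
                               ...) {
  if (!is.null(seed)) set.seed(seed)
  items <- rasch_items(beta = unname(object$beta_hat))
  spec <- sim_spec("rasch")
  lapply(seq_len(nsim), function(i) {
    theta <- object$latent_sd * rnorm(N)
    p <- irf_prob(theta, items)
    matrix(as.integer(matrix(runif(N * length(items$beta)),
                             N, length(items$beta)) < p),
           N, length(items$beta),
           dimnames = list(paste0("P", seq_len(N)), names(object$beta_hat)))
  })
}

# quadrature response probabilities at the fit: K x n
node_probs <- function(fit) {
  plogis(outer(fit$latent_sd * fit$gh$z, unname(fit$beta_hat), "-"))
}

# model-implied joint moment E[prod_{i in set} X_i] for arbitrary index sets
moments_of_sets <- function(P, w, sets) {
  vapply(sets, function(s) {
    pr <- P[, s[1L]]
    for (i in s[-1L]) pr <- pr * P[, i]
    sum(w * pr)
  }, 0)
}

#' Model-implied moments of the multivariate Bernoulli distribution
#'
#' Computes the moments of the item response vector implied by a fitted
#' marginal Rasch model: `E[prod_{i in A} X_i] = integral prod P_i(theta)
#' dPhi_sigma(theta)` by Gauss-Hermite quadrature (local independence given
#' theta).  Univariate and bivariate moments form the `pi_2` vector of the
#' M2 statistic; orders 3 and 4 are needed for its asymptotic covariance.
#'
#' @param fit a [rasch_mml()] fit.
#' @param order highest moment order, 1 to 4.
#' @return A list with `pi1` (univariate moments) and, as available,
#'   `pi2`, `pi3`, `pi4` — named vectors indexed by the item subsets in
#'   `combn` order.
#' @export
model_moments <- function(fit, order = 2L) {
  stopifnot(inherits(fit, "rasch_mml"), order >= 1L, order <= 4L)
  n <- length(fit$beta_hat)
  P <- node_probs(fit)
  w <- fit$gh$w
  out <- list(pi1 = stats::setNames(drop(crossprod(P, w)),
                                    names(fit$beta_hat)))
  for (k in 2:4) {
    if (order < k) break
    sets <- combn(n, k, simplify = FALSE)
    v <- moments_of_sets(P, w, sets)
    names(v) <- vapply(sets, function(s)
      paste(names(fit$beta_hat)[s], collapse = ":"), "")
    out[[paste0("pi", k)]] <- v
  }
  out
}
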