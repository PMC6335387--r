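# Conditional maximum likelihood estimation of Rasch item difficulties.
# The conditional likelihood given the raw scores is
#   prod_j eps_{x_j} / gamma_{r_j},
# with easiness eps_i = exp(-beta_i) and gamma_r the order-r elementary
# symmetric function (ESF) of the eps.  ESFs and their derivatives are
# computed in C++ by the numerically stable summation recursion.

#' Elementary symmetric functions
#'
#' Computes the elementary symmetric functions of orders 0..n of a positive
#' vector by the summation recursion, optionally together with the matrix of
#' first partial derivatives.
#'
#' @param epsilon positive numeric vector (item easiness parameters).
#' @param derivatives if `TRUE`, also return the `(n + 1) x n` matrix of
#'   partial derivatives of each order (rows 0..n) in each `epsilon_i`.
#' @return If `derivatives = FALSE`, a numeric vector of length `n + 1`
#'   holding orders 0..n (order 0 equals 1).  Otherwise a list with elements
#'   `esf` and `deriv`; the derivative of the order-r ESF in `epsilon_i`
#'   equals the order r-1 ESF of the vector with position i removed.
#' @export
elementary_symmetric <- function(epsilon, derivatives = FALSE) {
  epsilon <- as.numeric(epsilon)
  if (length(epsilon) < 1L || anyNA(epsilon) || any(epsilon <= 0))
    stop("epsilon must be a positive numeric vector")
  g <- esf_cpp(epsilon)
  if (!derivatives) return(g)
  n <- length(epsilon)
  sub <- esf_minus_one_cpp(epsilon)  # orders 0..n-1 of epsilon[-i]
  d <- rbind(0, sub)                 # d gamma_r / d eps_i = sub[r, i]
  rownames(d) <- NULL
  list(esf = g, deriv = d)
}

#' Fit the Rasch model by conditional maximum likelihood
#'
#' Estimates the item difficulties by maximizing the likelihood conditional
#' on the raw scores, which eliminates the person parameters through the
#' elementary symmetric functions.  Persons with extreme raw scores (0 or n)
#' carry no conditional information and are excluded (but counted in the
#' report).  The difficulties are normalized to sum to zero.
#'
#' Newton iterations with analytic gradient and Hessian and step-halving;
#' convergence when the gradient max-norm falls below `tol`.
#'
#' @param X 0/1 response matrix (persons x items).
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter iteration cap.
#' @return An object of class `rasch_cml` with components `beta_hat`
#'   (sum-zero difficulties), `cond_loglik`, `score_counts` (raw-score
#'   frequencies 0..n of all persons), `converged`, `n_used` (persons
#'   retained), `n_dropped`, `iterations`.
#' @export
rasch_cml <- function(X, tol = 1e-8, max_iter = 100L) {
  X <- as_response_matrix(X)
  n <- ncol(X)
  raw <- rowSums(X)
  keep <- raw > 0L & raw < n
  score_counts <- tabulate(raw + 1L, nbins = n + 1L)
  Xr <- X[keep, , drop = FALSE]
  if (nrow(Xr) == 0L)
    stop_degenerate("all persons have extreme raw scores (0 or n)")
  cs <- colSums(Xr)
  const <- which(cs == 0L | cs == nrow(Xr))
  if (length(const))
    stop_degenerate(
      paste0("item(s) constant after extreme-score removal: ",
             paste(colnames(X)[const], collapse = ", ")),
      items = const
    )
  cnt <- tabulate(rowSums(Xr) + 1L, nbins = n + 1L)
  cnt[c(1L, n + 1L)] <- 0
  p <- cs / nrow(Xr)
  beta <- log((1 - p) / p)
  beta <- beta - mean(beta)
  C <- rbind(diag(n - 1L), -1)  # sum-zero parameterization
  d <- cml_derivs_cpp(exp(-beta), cnt, cs)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    if (max(abs(d$grad)) < tol) {
      converged <- TRUE
      break
    }
    iter <- iter + 1L
    ga <- drop(crossprod(C, d$grad))
    Ha <- crossprod(C, d$hessian %*% C)
    step <- tryCatch(solve(Ha, ga), error = function(e) NULL)
    if (is.null(step))
      stop_nonconvergence("singular Hessian in CML Newton step", last = beta)
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + drop(C %*% (-step / 2^h))
      cand <- cand - mean(cand)
      dc <- cml_derivs_cpp(exp(-cand), cnt, cs)
      # tolerate rounding-level decreases: near the optimum the Newton
      # improvement falls below the fp noise of a log-likelihood of size N
      if (is.finite(dc$loglik) &&
          dc$loglik >= d$loglik - 1e-10 * max(1, abs(d$loglik))) {
        beta <- cand
        d <- dc
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop_nonconvergence("step-halving failed in CML iteration", last = beta)
  }
  if (!converged && max(abs(d$grad)) >= tol)
    stop_nonconvergence(
      sprintf("CML did not converge in %d iterations (grad max %.2e)",
              max_iter, max(abs(d$grad))),
      last = beta
    )
  structure(
    list(beta_hat = stats::setNames(beta, colnames(X)),
         cond_loglik = d$loglik,
         score_counts = stats::setNames(score_counts, 0:n),
         converged = TRUE,
         n_used = nrow(Xr),
         n_dropped = sum(!keep),
         iterations = iter,
         call = match.call()),
    class = "rasch_cml"
  )
}

#' @export
print.rasch_cml <- function(x, digits = 4, ...) {
  cat("Rasch model, conditional maximum likelihood\n")
  cat(sprintf("  persons used: %d (%d extreme scorers excluded)\n",
              x$n_used, x$n_dropped))
  cat(sprintf("  conditional log-likelihood: %.*f\n", digits, x$cond_loglik))
  cat("  item difficulties (sum-zero):\n")
  print(round(x$beta_hat, digits))
  invisible(x)
}

#' @export
coef.rasch_cml <- function(object, ...) object$beta_hat

#' @export
logLik.rasch_cml <- function(object, ...) {
  structure(object$cond_loglik, df = length(object$beta_hat) - 1L,
            nobs = object$n_used, class = "logLik")
}

#' @export
summary.rasch_cml <- function(object, ...) {
  print(object, ...)
  invisible(object)
}
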