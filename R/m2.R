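# The limited-information M2 statistic: quadratic form in the residuals
# between sample and model-implied moments up to order 2, weighted so that
# the uncertainty from parameter estimation is projected out.

# cache of subset bookkeeping per test length n:
#  sets2  : the s = n + choose(n, 2) moment index sets (singles, then pairs)
#  allsets: every subset of size 1..4 reachable as a union of two sets2
#  uidx   : s x s matrix indexing allsets at the union of each pair
.m2_cache <- new.env(parent = emptyenv())

subset_key <- function(s) {
  # bit-mask key split over two 25-bit words, exact in doubles
  lo <- sum(2^(s[s <= 25L] - 1L))
  hi <- sum(2^(s[s > 25L] - 26L))
  lo + hi * 2^26
}

m2_bookkeeping <- function(n) {
  key <- as.character(n)
  if (!is.null(.m2_cache[[key]])) return(.m2_cache[[key]])
  sets2 <- c(as.list(seq_len(n)), combn(n, 2L, simplify = FALSE))
  s <- length(sets2)
  unions <- vector("list", s * s)
  for (a in seq_len(s)) for (b in seq_len(s))
    unions[[(a - 1L) * s + b]] <- sort(unique(c(sets2[[a]], sets2[[b]])))
  ukeys <- vapply(unions, subset_key, 0)
  allkeys <- sort(unique(ukeys))
  allsets <- unions[match(allkeys, ukeys)]
  uidx <- matrix(match(ukeys, allkeys), s, s, byrow = TRUE)
  out <- list(sets2 = sets2, s = s, allsets = allsets, uidx = uidx)
  .m2_cache[[key]] <- out
  out
}

#' M2 limited-information goodness-of-fit test
#'
#' Computes the Maydeu-Olivares and Joe M2 statistic for a Rasch model
#' fitted by marginal maximum likelihood: with `e = p2 - pi2` the residual
#' between the sample and model-implied univariate and bivariate moments
#' (length `s = n + n(n-1)/2`),
#' `M2 = N e' C e`, where `C = Xi^-1 - Xi^-1 D (D' Xi^-1 D)^-1 D' Xi^-1`,
#' `Xi` is the asymptotic covariance of the sample moments evaluated at the
#' fitted model and `D` the Jacobian of the model moments in the `q = n + 1`
#' parameters.  The statistic is evaluated in the algebraically equivalent
#' but numerically stabler orthogonal-complement form
#' `N e' U (U' Xi U)^-1 U' e`, with `U` an orthonormal basis of the null
#' space of `D'`.  Under the Rasch model M2 is asymptotically chi-square
#' with `s - q` degrees of freedom.
#'
#' @param X 0/1 response matrix.
#' @param fit a converged [rasch_mml()] fit of `X`; refitted when `NULL`.
#' @param keep_matrices if `TRUE`, return `e`, `Xi`, `Delta` in the result
#'   (used for cross-checks; sizeable for long tests).
#' @return An object of classes `rasch_gof` and `htest` with the statistic,
#'   degrees of freedom `s - q`, upper-tail p-value, and `s`, `q`.
#' @export
m2_test <- function(X, fit = NULL, keep_matrices = FALSE) {
  dname <- deparse(substitute(X))
  X <- as_response_matrix(X)
  if (ncol(X) < 3L)
    stop("M2 needs at least 3 items (s must exceed q = n + 1)")
  if (is.null(fit)) fit <- rasch_mml(X)
  stopifnot(inherits(fit, "rasch_mml"))
  n <- length(fit$beta_hat)
  if (ncol(X) != n) stop("fit and matrix disagree on the number of items")
  N <- nrow(X)
  bk <- m2_bookkeeping(n)
  s <- bk$s
  q <- fit$q
  # sample moments: item means, then pairwise joint means in combn order
  cp <- crossprod(X) / N
  p2 <- c(diag(cp), cp[lower.tri(cp)])
  # model moments for every subset needed (orders 1..4)
  P <- node_probs(fit)
  w <- fit$gh$w
  momall <- moments_of_sets(P, w, bk$allsets)
  pi2 <- momall[bk$uidx[cbind(seq_len(s), seq_len(s))]]
  e <- p2 - pi2
  # Xi_ab = pi_{a u b} - pi_a pi_b
  Xi <- momall[bk$uidx] - outer(pi2, pi2)
  # Jacobian: columns beta_1..beta_n, then sigma
  Q <- 1 - P
  z <- fit$gh$z
  Delta <- matrix(0, s, q)
  for (a in seq_len(s)) {
    set <- bk$sets2[[a]]
    pr <- P[, set[1L]]
    for (i in set[-1L]) pr <- pr * P[, i]
    qs <- Q[, set, drop = FALSE]
    for (i in seq_along(set))
      Delta[a, set[i]] <- -sum(w * qs[, i] * pr)
    Delta[a, q] <- sum(w * z * rowSums(qs) * pr)
  }
  qrD <- qr(Delta)
  if (qrD$rank < q)
    stop("moment Jacobian is rank deficient; model not identified from ",
         "second-order moments")
  U <- qr.Q(qrD, complete = TRUE)[, (q + 1L):s, drop = FALSE]
  W <- crossprod(U, Xi %*% U)
  rc <- rcond(W)
  if (!is.finite(rc) || rc < 1e-12)
    stop(sprintf(
      "projected moment covariance numerically singular (rcond %.2e)", rc))
  eU <- drop(crossprod(U, e))
  stat <- N * drop(crossprod(eU, solve(W, eU)))
  df <- s - q
  new_rasch_gof(
    statistic = c(M2 = stat),
    df = c(df = df),
    p = pchisq(max(stat, 0), df = df, lower.tail = FALSE),
    method = "Maydeu-Olivares and Joe M2 limited-information test",
    tag = "M2",
    data.name = dname,
    n_items = n,
    n_persons = N,
    extra = c(list(s = s, q = q, latent_sd = fit$latent_sd),
              if (keep_matrices) list(e = e, Xi = Xi, Delta = Delta))
  )
}
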