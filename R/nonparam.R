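# Ponocny's nonparametric T10 (subgroup invariance) and T11 (local
# dependence) statistics with bootstrap p-values over the margin-fixed
# sample.

#' T10: subgroup-invariance statistic
#'
#' For each unordered item pair (i, j), let `N_ij(h)` be the number of
#' persons in the high score group answering item i positively and item j
#' negatively, and `N_ij(l)` the analogous count in the low group.  T10 sums
#' `|N_ij(h) * N_ji(l) - N_ij(l) * N_ji(h)|` over the pairs; large values
#' indicate that the item ordering differs between score groups.
#'
#' @param X 0/1 response matrix.
#' @param split a [median_split()]-style grouping (computed on the observed
#'   matrix; row sums are preserved by the margin-fixed sampler, so the same
#'   split applies to every sampled matrix).
#' @return The nonnegative statistic value.
#' @export
t10_statistic <- function(X, split = median_split(X)) {
  X <- as_response_matrix(X)
  hi <- which(split$group == 2L)
  lo <- which(split$group == 1L)
  Nh <- crossprod(X[hi, , drop = FALSE], 1L - X[hi, , drop = FALSE])
  Nl <- crossprod(X[lo, , drop = FALSE], 1L - X[lo, , drop = FALSE])
  D <- abs(Nh * t(Nl) - Nl * t(Nh))
  sum(D[upper.tri(D)])
}

#' T11: local-dependence statistic
#'
#' Sums `|r_ij - rho_ij|` over unordered item pairs, where `r_ij` is the
#' observed product-moment (phi) correlation of the 0/1 item columns and
#' `rho_ij` its expected value under the Rasch null, estimated as the mean
#' inter-item correlation over the margin-fixed sample.
#'
#' @param X 0/1 response matrix with non-constant columns.
#' @param rho_null n x n matrix of null inter-item correlations.
#' @return The nonnegative statistic value.
#' @export
t11_statistic <- function(X, rho_null) {
  X <- as_response_matrix(X)
  cs <- colSums(X)
  const <- which(cs == 0L | cs == nrow(X))
  if (length(const))
    stop_degenerate(
      paste0("constant item column(s): ",
             paste(colnames(X)[const], collapse = ", ")),
      items = const
    )
  if (!is.matrix(rho_null) || any(dim(rho_null) != ncol(X)))
    stop("rho_null must be an n x n matrix")
  d <- abs(cor(X) - rho_null)
  sum(d[upper.tri(d)])
}

# add-one bootstrap p-value; avoids exact zeros
bootstrap_p <- function(obs, null_stats) {
  (1 + sum(null_stats >= obs)) / (length(null_stats) + 1)
}

# evaluate T10 and/or T11 on an observed matrix and a margin-fixed sample;
# shared by ponocny_test() and the study harness (one sample, both tests)
ponocny_from_sample <- function(X, smp, which = c("T10", "T11")) {
  which <- match.arg(which, c("T10", "T11"), several.ok = TRUE)
  out <- list(singleton = smp$singleton)
  mats <- smp$matrices
  # row sums are invariant under rectangle swaps, so the observed median
  # split carries over to every sampled matrix unchanged
  stopifnot(identical(rowSums(mats[[1L]]), rowSums(X)))
  if ("T10" %in% which) {
    split <- median_split(X)
    obs <- t10_statistic(X, split)
    null <- vapply(mats, t10_statistic, 0, split = split)
    out$T10 <- list(observed = obs, null = null,
                    p = bootstrap_p(obs, null))
  }
  if ("T11" %in% which) {
    cs <- colSums(X)
    if (any(cs == 0L | cs == nrow(X)))
      stop_degenerate("constant item column(s); T11 undefined",
                      items = which(cs == 0L | cs == nrow(X)))
    cors <- lapply(mats, cor)
    rho_null <- Reduce(`+`, cors) / length(cors)
    obs <- t11_statistic(X, rho_null)
    null <- vapply(seq_along(mats), function(b) {
      d <- abs(cors[[b]] - rho_null)
      sum(d[upper.tri(d)])
    }, 0)
    out$T11 <- list(observed = obs, null = null,
                    p = bootstrap_p(obs, null), rho_null = rho_null)
  }
  out
}

#' Nonparametric quasi-exact test of the Rasch model (T10 / T11)
#'
#' Draws `B` matrices uniformly from the set of 0/1 matrices with the row
#' and column sums of `X` (see [sample_fixed_margins()]), evaluates the
#' chosen statistic on the observed matrix and on every draw, and reports
#' the add-one bootstrap p-value `(1 + #(null >= observed)) / (B + 1)`.
#' For T11 the null correlation matrix `rho` is the element-wise mean over
#' the same `B` draws, and both the observed and the null statistics are
#' evaluated against that common `rho`.  No asymptotic reference
#' distribution is involved, so no degrees of freedom are reported.
#'
#' If the margin-fixed reference set is a singleton the p-value is 1 and a
#' warning flag is set.
#'
#' @param X 0/1 response matrix.
#' @param statistic `"T10"` or `"T11"`.
#' @param B number of bootstrap matrices (the study default is 500; 300 is
#'   used inside large simulation grids).
#' @param burn_in,thin,seed passed to [sample_fixed_margins()].
#' @return An object of classes `rasch_gof` and `htest` with the statistic,
#'   p-value, the null statistic values (`null_stats`) and, for T11, the
#'   null correlation matrix (`rho_null`).
#' @export
ponocny_test <- function(X, statistic = c("T10", "T11"), B = 500L,
                         burn_in = NULL, thin = NULL, seed = NULL) {
  statistic <- match.arg(statistic)
  dname <- deparse(substitute(X))
  X <- as_response_matrix(X)
  smp <- sample_fixed_margins(X, B = B, burn_in = burn_in, thin = thin,
                              seed = seed)
  res <- ponocny_from_sample(X, smp, which = statistic)
  r <- res[[statistic]]
  p <- if (res$singleton) 1 else r$p
  out <- new_rasch_gof(
    statistic = stats::setNames(r$observed, statistic),
    df = NULL,
    p = p,
    method = sprintf(
      "Ponocny %s quasi-exact test (%d margin-fixed bootstrap samples)",
      statistic, length(smp$matrices)),
    tag = statistic,
    data.name = dname,
    n_items = ncol(X),
    n_persons = nrow(X),
    extra = list(B = length(smp$matrices), null_stats = r$null,
                 singleton = res$singleton,
                 rho_null = r$rho_null)
  )
  if (res$singleton)
    warning("margin-fixed reference set is a singleton; p-value is 1")
  out
}
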