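# Uniform sampling of 0/1 matrices with the observed row and column sums:
# the null reference set for the nonparametric tests.

#' Sample binary matrices with fixed margins
#'
#' Runs a rectangle-swap Markov chain on the set of 0/1 matrices sharing the
#' row and column sums of `X`: each proposal draws two row and two column
#' indices (independently, with replacement — coinciding indices are a hold
#' move, which keeps the chain aperiodic); if the selected 2x2 submatrix is
#' a checkerboard (`[[1,0],[0,1]]` or `[[0,1],[1,0]]`) it is flipped,
#' otherwise the state is kept.  The proposal kernel is symmetric, so the
#' stationary distribution is uniform on the margin-fixed set.
#'
#' Defaults scale with the matrix mass: `burn_in = 100 * sum(X)` proposals
#' and `thin = 2 * sum(X)` proposals between retained draws.
#'
#' If no swappable tetrad exists the reference set is a singleton; the
#' sample then consists of copies of `X` and is flagged (all bootstrap
#' p-values become 1).
#'
#' @param X 0/1 response matrix.
#' @param B number of matrices to retain.
#' @param burn_in proposals discarded before the first retained draw.
#' @param thin proposals between retained draws.
#' @param seed optional integer seed (calls `set.seed`); if `NULL` the
#'   current RNG stream is used.
#' @return An object of class `margin_sample`: list with `matrices` (length
#'   `B`), `burn_in`, `thin`, `seed`, `singleton`.
#' @export
sample_fixed_margins <- function(X, B = 500L, burn_in = NULL, thin = NULL,
                                 seed = NULL) {
  X <- as_response_matrix(X)
  if (length(B) != 1L || !is.finite(B) || B < 1)
    stop("B must be a positive integer")
  B <- as.integer(B)
  mass <- sum(X)
  if (is.null(burn_in)) burn_in <- 100 * mass
  if (is.null(thin)) thin <- max(1, 2 * mass)
  if (burn_in < 0) stop("burn_in must be nonnegative")
  if (thin < 1) stop("thin must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  # a swappable tetrad exists iff some ordered column pair shows both the
  # (1,0) and the (0,1) row pattern
  A <- crossprod(X, 1L - X)
  singleton <- !any(A > 0L & t(A) > 0L)
  mats <- sample_margins_cpp(X, B, as.numeric(burn_in), as.numeric(thin))
  dn <- dimnames(X)
  mats <- lapply(mats, function(m) { dimnames(m) <- dn; m })
  structure(
    list(matrices = mats, burn_in = burn_in, thin = thin,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         singleton = singleton),
    class = "margin_sample"
  )
}

#' @export
print.margin_sample <- function(x, ...) {
  d <- dim(x$matrices[[1L]])
  cat(sprintf("Margin-fixed sample: %d matrices of %d x %d (burn-in %g, thin %g)\n",
              length(x$matrices), d[1L], d[2L], x$burn_in, x$thin))
  if (x$singleton)
    cat("  note: reference set is a singleton; all draws equal the input\n")
  invisible(x)
}
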