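# Independent oracles used across the suite.  These deliberately take the
# slow, enumerative route so they share no code with the implementation.

# elementary symmetric functions by explicit subset enumeration (2^n)
esf_bruteforce <- function(eps) {
  n <- length(eps)
  out <- numeric(n + 1)
  out[1] <- 1
  for (r in seq_len(n)) {
    subs <- combn(n, r)
    out[r + 1] <- sum(apply(subs, 2, function(s) prod(eps[s])))
  }
  out
}

# conditional Rasch log-likelihood at sum-zero beta, by direct evaluation
cond_loglik_oracle <- function(X, beta) {
  n <- ncol(X)
  raw <- rowSums(X)
  keep <- raw > 0 & raw < n
  Xr <- X[keep, , drop = FALSE]
  eps <- exp(-beta)
  g <- esf_bruteforce(eps)
  sum(Xr %*% log(eps)) - sum(log(g[rowSums(Xr) + 1]))
}

# all 0/1 matrices with given margins, by exhaustive enumeration
enumerate_margin_set <- function(rs, cs) {
  N <- length(rs); n <- length(cs)
  cells <- as.matrix(expand.grid(rep(list(0:1), N * n)))
  keep <- apply(cells, 1, function(v) {
    m <- matrix(v, N, n)
    all(rowSums(m) == rs) && all(colSums(m) == cs)
  })
  lapply(which(keep), function(i) matrix(cells[i, ], N, n))
}

# canonical string key of a 0/1 matrix (for frequency tabulation)
matrix_key <- function(m) paste(as.integer(m), collapse = "")

# T10 by raw tabulation of response patterns, no crossprod shortcuts
t10_oracle <- function(X, group) {
  n <- ncol(X)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    Nh_ij <- sum(group == 2 & X[, i] == 1 & X[, j] == 0, na.rm = TRUE)
    Nh_ji <- sum(group == 2 & X[, j] == 1 & X[, i] == 0, na.rm = TRUE)
    Nl_ij <- sum(group == 1 & X[, i] == 1 & X[, j] == 0, na.rm = TRUE)
    Nl_ji <- sum(group == 1 & X[, j] == 1 & X[, i] == 0, na.rm = TRUE)
    tot <- tot + abs(Nh_ij * Nl_ji - Nl_ij * Nh_ji)
  }
  tot
}

# a score_split with hand-chosen labels (1 = low, 2 = high, NA = excluded)
manual_split <- function(group) {
  structure(list(group = as.integer(group), G = 2L, median = NA,
                 rule = "manual"), class = "score_split")
}

# small Rasch dataset for reuse
make_null_data <- function(N = 200, n = 10, seed = 1) {
  set.seed(seed)
  items <- draw_item_difficulties(n)
  X <- sim_responses(sim_spec("rasch"), N, items)
  list(X = X, items = items)
}
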