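# Andersen's likelihood-ratio test: CML fits in score groups against the
# total-sample CML fit.

#' Median split of respondents by raw score
#'
#' Partitions the retained persons into two score groups: persons whose raw
#' score is at least the median of the retained raw scores go to the high
#' group, the rest to the low group.  Persons with extreme raw scores (0 or
#' n) are excluded before the median is computed; they receive `NA` labels.
#' Ties at the median go to the high group, the convention the T10 statistic
#' uses, so the same split serves the LR and T10 tests.
#'
#' @param X 0/1 response matrix.
#' @return An object of class `score_split`: list with `group` (integer 1 =
#'   low, 2 = high, `NA` = excluded), `G = 2`, `median`, `rule`.
#' @export
median_split <- function(X) {
  X <- as_response_matrix(X)
  n <- ncol(X)
  raw <- rowSums(X)
  keep <- raw > 0L & raw < n
  if (!any(keep))
    stop_degenerate("no persons with non-extreme raw scores")
  med <- median(raw[keep])
  group <- rep(NA_integer_, nrow(X))
  group[keep] <- ifelse(raw[keep] >= med, 2L, 1L)
  if (!any(group == 1L, na.rm = TRUE) || !any(group == 2L, na.rm = TRUE))
    stop_degenerate("degenerate median split: all retained persons on one side")
  structure(
    list(group = group, G = 2L, median = med,
         rule = "raw score >= median -> high group; extreme scorers excluded"),
    class = "score_split"
  )
}

#' @export
print.score_split <- function(x, ...) {
  cat(sprintf("Score split into %d groups (%s)\n", x$G, x$rule))
  print(table(factor(x$group, levels = seq_len(x$G),
                     labels = c("low", "high")[seq_len(x$G)]),
              useNA = "ifany"))
  invisible(x)
}

#' Andersen's likelihood-ratio test for the Rasch model
#'
#' Computes `LR = 2 * (sum_c lnL_c(beta_c) - lnL(beta))`, comparing the
#' conditional likelihoods of CML fits within score groups with the
#' total-sample fit.  Under the Rasch model LR is asymptotically chi-square
#' with degrees of freedom equal to the number of parameters estimated in
#' the groups minus the number estimated in the total sample, i.e.
#' `(G - 1) * (m - 1)` for a common set of m items.
#'
#' Items that are constant within any group (or overall) after extreme-score
#' removal are dropped from all fits so that the parameter spaces remain
#' nested; dropped items are recorded and the degrees of freedom adjusted.
#'
#' @param X 0/1 response matrix.
#' @param split a [median_split()]-style grouping; defaults to the median
#'   split of `X`.
#' @return An object of classes `rasch_gof` and `htest` with the statistic,
#'   degrees of freedom, upper-tail p-value, and diagnostics
#'   (`items_dropped`, `group_fits`).
#' @export
lr_test <- function(X, split = median_split(X)) {
  dname <- deparse(substitute(X))
  X <- as_response_matrix(X)
  n <- ncol(X)
  groups <- sort(unique(split$group[!is.na(split$group)]))
  if (length(groups) < 2L)
    stop_degenerate("need at least two nonempty score groups")
  items <- seq_len(n)
  dropped <- integer(0)
  fits <- NULL
  for (round in seq_len(n)) {
    bad <- integer(0)
    fits <- vector("list", length(groups) + 1L)
    for (k in seq_along(fits)) {
      Xk <- if (k == 1L) X[, items, drop = FALSE]
            else X[which(split$group == groups[k - 1L]), items, drop = FALSE]
      f <- tryCatch(rasch_cml(Xk), raschgof_degenerate = function(e) e)
      if (inherits(f, "raschgof_degenerate")) {
        if (length(f$items) == 0L) stop(f)
        bad <- union(bad, items[f$items])
        f <- NULL
      }
      fits[[k]] <- f
    }
    if (!length(bad)) break
    dropped <- union(dropped, bad)
    items <- setdiff(items, bad)
    if (length(items) < 2L)
      stop_degenerate("fewer than 2 usable items remain for the LR test")
  }
  if (any(vapply(fits, is.null, logical(1))))
    stop_degenerate("group fits did not stabilize")
  m <- length(items)
  total <- fits[[1L]]
  group_fits <- fits[-1L]
  stat <- 2 * (sum(vapply(group_fits, function(f) f$cond_loglik, 0)) -
                 total$cond_loglik)
  df <- (length(groups) - 1L) * (m - 1L)
  p <- pchisq(max(stat, 0), df = df, lower.tail = FALSE)
  new_rasch_gof(
    statistic = c(LR = stat),
    df = c(df = df),
    p = p,
    method = "Andersen likelihood-ratio test (median score split)",
    tag = "LR",
    data.name = dname,
    n_items = m,
    n_persons = total$n_used,
    extra = list(items_dropped = colnames(X)[dropped],
                 total_fit = total, group_fits = group_fits)
  )
}
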