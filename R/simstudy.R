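# Monte-Carlo harness: condition grid x generating models x four tests ->
# rejection-rate tables.

#' Define a simulation condition
#'
#' One cell of the Monte-Carlo design: a generating model, a sample size,
#' a test length, a replication count, a seed and the nominal alpha levels.
#' Within a condition the item parameters are drawn once (from the
#' condition seed) and held fixed; person parameters are redrawn every
#' replication from per-replication seeds derived from the condition seed,
#' which makes whole tables reproducible and independent of execution
#' order.
#'
#' @param spec a [sim_spec()] object.
#' @param N sample size (the study grid uses 100, 200, 500, 1000).
#' @param n test length (the study grid uses 10, 30, 50).
#' @param reps number of replications (the full study used 5000; the
#'   package default is desk-scale).
#' @param seed integer condition seed.
#' @param alpha nominal levels.
#' @param B bootstrap sample size for the nonparametric tests.
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(spec, N, n, reps = 500L, seed = 1L,
                          alpha = c(0.05, 0.01), B = 300L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (reps < 1L) stop("reps must be at least 1")
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha levels must lie in (0, 1)")
  if (n < 2L) stop("need at least 2 items")
  structure(
    list(spec = spec, N = as.integer(N), n = as.integer(n),
         reps = as.integer(reps), seed = as.integer(seed),
         alpha = as.numeric(alpha), B = as.integer(B)),
    class = "sim_condition"
  )
}

cond_key <- function(cond) {
  pars <- cond$spec[setdiff(names(cond$spec), "family")]
  paste(cond$spec$family, cond$N, cond$n, cond$reps, cond$seed,
        paste(names(pars), unlist(pars), sep = "=", collapse = ","),
        sep = "|")
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf("Condition: %s, N = %d, n = %d, reps = %d, seed = %d, B = %d\n",
              x$spec$family, x$N, x$n, x$reps, x$seed, x$B))
  invisible(x)
}

# all p-values for one replication; NA marks a test failure
run_one_replication <- function(X, tests, B, sampler_seed) {
  p <- stats::setNames(rep(NA_real_, length(tests)), tests)
  if ("LR" %in% tests)
    p["LR"] <- tryCatch(lr_test(X)$p.value, error = function(e) NA_real_)
  if ("M2" %in% tests)
    p["M2"] <- tryCatch(m2_test(X)$p.value, error = function(e) NA_real_)
  np <- intersect(c("T10", "T11"), tests)
  if (length(np)) {
    res <- tryCatch({
      smp <- sample_fixed_margins(X, B = B, seed = sampler_seed)
      ponocny_from_sample(X, smp, which = np)
    }, error = function(e) NULL)
    for (t in np)
      p[t] <- if (is.null(res)) NA_real_
              else if (res$singleton) 1 else res[[t]]$p
  }
  p
}

#' Run one simulation condition
#'
#' Draws the condition's item parameters once, then per replication
#' generates a response matrix, runs each requested test and records
#' whether `p < alpha`.  Replications where a test errors (degenerate data,
#' non-convergence) are excluded from that test's denominator and counted
#' as failures.
#'
#' @param cond a [sim_condition()].
#' @param tests subset of `c("LR", "T10", "T11", "M2")`.  T10 and T11 share
#'   one margin-fixed sample per replication.
#' @return A `data.frame` (one row per test x alpha) with columns `family`,
#'   `params`, `N`, `n`, `test`, `alpha`, `rate`, `mcse`, `reps_used`,
#'   `failures`, `reps`.
#' @export
run_condition <- function(cond, tests = c("LR", "T10", "T11", "M2")) {
  stopifnot(inherits(cond, "sim_condition"))
  if (length(tests) == 0L) return(empty_rejection_table())
  tests <- match.arg(tests, c("LR", "T10", "T11", "M2"), several.ok = TRUE)
  set.seed(cond$seed)
  items <- draw_condition_items(cond$spec, cond$n)
  rep_seeds <- sample.int(2147483646L, cond$reps)
  pmat <- matrix(NA_real_, cond$reps, length(tests),
                 dimnames = list(NULL, tests))
  for (rep in seq_len(cond$reps)) {
    set.seed(rep_seeds[rep])
    X <- generate_dataset(cond$spec, cond$N, items)
    pmat[rep, ] <- run_one_replication(
      X, tests, B = cond$B,
      sampler_seed = rep_seeds[rep] %% 1999999973L + 1L
    )
  }
  pars <- cond$spec[setdiff(names(cond$spec), "family")]
  rows <- expand.grid(test = tests, alpha = cond$alpha,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    pv <- pmat[, rows$test[i]]
    ok <- !is.na(pv)
    used <- sum(ok)
    rate <- if (used) mean(pv[ok] < rows$alpha[i]) else NA_real_
    data.frame(
      family = cond$spec$family,
      params = paste(names(pars), unlist(pars), sep = "=", collapse = ","),
      N = cond$N, n = cond$n,
      test = rows$test[i], alpha = rows$alpha[i],
      rate = rate,
      mcse = if (used) sqrt(rate * (1 - rate) / used) else NA_real_,
      reps_used = used,
      failures = sum(!ok),
      reps = cond$reps,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

empty_rejection_table <- function() {
  data.frame(family = character(0), params = character(0),
             N = integer(0), n = integer(0), test = character(0),
             alpha = numeric(0), rate = numeric(0), mcse = numeric(0),
             reps_used = integer(0), failures = integer(0),
             reps = integer(0), stringsAsFactors = FALSE)
}

#' Run a grid of simulation conditions
#'
#' Runs [run_condition()] over a list of conditions and concatenates the
#' rejection tables.  Each condition seeds itself, so the result is
#' deterministic given the seeds regardless of execution order.
#'
#' @param conditions list of [sim_condition()] objects with distinct keys.
#' @param tests subset of `c("LR", "T10", "T11", "M2")`.
#' @return The combined rejection-rate `data.frame`.
#' @export
run_grid <- function(conditions, tests = c("LR", "T10", "T11", "M2")) {
  stopifnot(all(vapply(conditions, inherits, TRUE, "sim_condition")))
  keys <- vapply(conditions, cond_key, "")
  if (anyDuplicated(keys))
    stop("duplicate condition keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  do.call(rbind, c(lapply(conditions, run_condition, tests = tests),
                   list(empty_rejection_table())))
}
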