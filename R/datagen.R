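# Data generators: the Rasch null and the five violation models used in the
# type-I-error / power study.

#' Item parameter sets for dichotomous IRT generators
#'
#' Container for per-item parameters of the generating models: difficulty
#' `beta` (logit scale), discrimination `alpha` (positive, 1 under the Rasch
#' model), lower asymptote `gamma` (pseudo-guessing, in `[0, 1)`), the latent
#' `dimension` an item loads on (1 or 2), and a latent-class difficulty shift
#' `dif_shift` (added to `beta` for members of the shifted class).
#'
#' @param beta numeric vector of item difficulties, length at least 2.
#' @param alpha positive discriminations, recycled to `length(beta)`.
#' @param gamma lower asymptotes in `[0, 1)`, recycled.
#' @param dimension integer 1 or 2 per item, recycled.
#' @param dif_shift per-item difficulty shift applied in the shifted latent
#'   class, recycled.
#' @return An object of class `rasch_items`.
#' @export
rasch_items <- function(beta, alpha = 1, gamma = 0, dimension = 1L,
                        dif_shift = 0) {
  beta <- as.numeric(beta)
  n <- length(beta)
  if (n < 2L) stop("need at least 2 items")
  if (!all(is.finite(beta))) stop("item difficulties must be finite")
  alpha <- rep_len(as.numeric(alpha), n)
  gamma <- rep_len(as.numeric(gamma), n)
  dimension <- rep_len(as.integer(dimension), n)
  dif_shift <- rep_len(as.numeric(dif_shift), n)
  if (any(alpha <= 0)) stop("discriminations must be positive")
  if (any(gamma < 0 | gamma >= 1)) stop("pseudo-guessing must lie in [0, 1)")
  if (!all(dimension %in% 1:2)) stop("dimension labels must be 1 or 2")
  structure(
    list(beta = beta, alpha = alpha, gamma = gamma,
         dimension = dimension, dif_shift = dif_shift),
    class = "rasch_items"
  )
}

#' @export
print.rasch_items <- function(x, ...) {
  cat("Item parameters for", length(x$beta), "items\n")
  print(data.frame(beta = x$beta, alpha = x$alpha, gamma = x$gamma,
                   dimension = x$dimension, dif_shift = x$dif_shift))
  invisible(x)
}

#' Draw standard-normal item difficulties
#'
#' Draws item difficulties i.i.d. from N(0, 1), with unit discriminations and
#' zero lower asymptotes, the configuration used for the null (Rasch) data in
#' the simulation studies.  In a simulation condition the item parameters are
#' drawn once and held fixed over replications; seed the R RNG before calling
#' to make the draw reproducible.
#'
#' @param n number of items, at least 2.
#' @return A [rasch_items()] object.
#' @export
draw_item_difficulties <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2)
    stop("need at least 2 items")
  rasch_items(beta = rnorm(as.integer(n)))
}

#' Generating-model specification
#'
#' Describes one of the six data-generating models of the simulation study:
#' `rasch` (the null), `surface_ld` (Rasch data post-processed so that a
#' prerequisite item is overwritten as solved), `multidim` (two correlated
#' standard-normal traits, each driving one half of the items),
#' `mixed_rasch` (a latent class whose members see shifted difficulties on a
#' leading block of items), `twopl` (log-normal discriminations) and
#' `guessing` (constant nonzero lower asymptote).
#'
#' @param family one of `"rasch"`, `"surface_ld"`, `"multidim"`,
#'   `"mixed_rasch"`, `"twopl"`, `"guessing"`.
#' @param ... family parameters overriding the defaults:
#'   `overwrite_prob` (surface_ld, default 0.9; the study levels are 0.9
#'   "major" and 0.8 "minor"), `r` (multidim trait correlation, default 0.3;
#'   levels 0.3/0.7), `dif_frac`, `dif_shift`, `class_prop` (mixed_rasch,
#'   defaults 0.4, -0.8, 0.4; `dif_frac` levels 0.2/0.4), `log_var` (twopl
#'   log-scale variance of the discriminations, default 0.25; levels
#'   0.09/0.25), `gamma` (guessing, default 0.25; levels 0.1/0.25).
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(family = c("rasch", "surface_ld", "multidim",
                                "mixed_rasch", "twopl", "guessing"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    rasch = list(),
    surface_ld = list(overwrite_prob = 0.9, prereq_item = 1L,
                      dependent_item = 2L, prereq_beta = -0.626,
                      dependent_beta = 0.184),
    multidim = list(r = 0.3),
    mixed_rasch = list(dif_frac = 0.4, dif_shift = -0.8, class_prop = 0.4),
    twopl = list(log_var = 0.25),
    guessing = list(gamma = 0.25)
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "))
  p <- modifyList(defaults, extra)
  if (family == "surface_ld" &&
      (p$overwrite_prob <= 0 || p$overwrite_prob > 1))
    stop("overwrite_prob must lie in (0, 1]")
  if (family == "multidim" && (p$r < -1 || p$r > 1))
    stop("trait correlation must lie in [-1, 1]")
  if (family == "mixed_rasch" &&
      (p$dif_frac <= 0 || p$dif_frac > 1 || p$class_prop <= 0 || p$class_prop >= 1))
    stop("dif_frac must lie in (0, 1], class_prop in (0, 1)")
  if (family == "twopl" && p$log_var < 0)
    stop("log_var must be nonnegative")
  if (family == "guessing" && (p$gamma < 0 || p$gamma >= 1))
    stop("gamma must lie in [0, 1)")
  structure(c(list(family = family), p), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("Generating model:", x$family, "\n")
  if (length(pars))
    cat(paste(names(pars), unlist(pars), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Item response probabilities of the generating models
#'
#' Evaluates `gamma_i + (1 - gamma_i) * plogis(alpha_i * (theta - beta_i))`,
#' which covers the Rasch model (`alpha = 1`, `gamma = 0`), the 2PL model and
#' the 1PL model with pseudo-guessing.
#'
#' @param theta abilities: a vector of length N, or an N x n matrix giving
#'   the ability value that drives each response (used for multidimensional
#'   or latent-class generation).
#' @param items a [rasch_items()] object.
#' @return An N x n matrix of response probabilities.
#' @export
irf_prob <- function(theta, items) {
  n <- length(items$beta)
  Th <- if (is.matrix(theta)) theta else matrix(theta, length(theta), n)
  if (ncol(Th) != n) stop("theta matrix must have one column per item")
  eta <- sweep(Th, 2L, items$beta, "-")
  eta <- sweep(eta, 2L, items$alpha, "*")
  p <- plogis(eta)
  if (any(items$gamma > 0))
    p <- sweep(p, 2L, items$gamma, function(pp, gg) gg + (1 - gg) * pp)
  p
}

#' Draw the per-condition item parameters implied by a generating model
#'
#' Difficulties are always i.i.d. standard normal; on top of that the
#' family adds its fixed structure: `surface_ld` forces the prerequisite /
#' dependent difficulties (-0.626 and 0.184) into their positions,
#' `multidim` labels the first half of the items with trait 1 and the
#' second half with trait 2, `mixed_rasch` marks the leading
#' `round(dif_frac * n)` items with the class shift, `twopl` draws
#' log-normal discriminations (once per condition, like the difficulties),
#' and `guessing` sets the constant lower asymptote.  Seed the R RNG before
#' calling for a reproducible condition.
#'
#' @param spec a [sim_spec()] object.
#' @param n number of items.
#' @return A [rasch_items()] object.
#' @export
draw_condition_items <- function(spec, n) {
  items <- draw_item_difficulties(n)
  switch(spec$family,
    rasch = items,
    surface_ld = {
      items$beta[spec$prereq_item] <- spec$prereq_beta
      items$beta[spec$dependent_item] <- spec$dependent_beta
      items
    },
    multidim = {
      if (n %% 2L != 0L)
        stop("multidimensional generation needs an even number of items")
      items$dimension <- rep(1:2, each = n %/% 2L)
      items
    },
    mixed_rasch = {
      k <- round(spec$dif_frac * n)
      items$dif_shift <- c(rep(spec$dif_shift, k), rep(0, n - k))
      items
    },
    twopl = {
      items$alpha <- rlnorm(n, meanlog = 0, sdlog = sqrt(spec$log_var))
      items
    },
    guessing = {
      items$gamma <- rep(spec$gamma, n)
      items
    }
  )
}

#' Generate a response matrix under a generating model
#'
#' Draws one N x n matrix of Bernoulli responses.  Person parameters are
#' redrawn on every call (standard normal; for `multidim`, bivariate standard
#' normal with correlation `spec$r`, each trait driving the items whose
#' `dimension` label matches; for `mixed_rasch`, a latent Bernoulli
#' (`class_prop`) class indicator per person adds `dif_shift` to the shifted
#' items' difficulties).  Item parameters are taken from `items` and are
#' expected to be drawn once per simulation condition (see
#' [draw_condition_items()]).
#'
#' The `surface_ld` family is a post-processing step on Rasch data and is
#' deliberately rejected here; generate under `rasch` and call
#' [apply_surface_ld()].
#'
#' @param spec a [sim_spec()] object.
#' @param N number of persons.
#' @param items a [rasch_items()] object consistent with `spec`.
#' @return An integer N x n matrix of 0/1 responses with person/item labels,
#'   the drawn abilities in `attr(, "theta")` and, for `mixed_rasch`, the
#'   class indicator in `attr(, "latent_class")`.
#' @export
sim_responses <- function(spec, N, items) {
  stopifnot(inherits(spec, "sim_spec"), inherits(items, "rasch_items"))
  if (length(N) != 1L || !is.finite(N) || N < 1) stop("N must be positive")
  N <- as.integer(N)
  n <- length(items$beta)
  cls <- NULL
  if (spec$family == "surface_ld")
    stop("surface_ld is applied post hoc: generate under 'rasch' and call ",
         "apply_surface_ld()")
  if (spec$family == "multidim") {
    if (n %% 2L != 0L)
      stop("multidimensional generation needs an even number of items")
    if (!all(sort(unique(items$dimension)) == 1:2))
      stop("multidim items must carry dimension labels 1 and 2")
    z1 <- rnorm(N)
    z2 <- rnorm(N)
    th <- cbind(z1, spec$r * z1 + sqrt(1 - spec$r^2) * z2)
    Th <- th[, items$dimension, drop = FALSE]
    theta_attr <- th
  } else {
    theta <- rnorm(N)
    Th <- matrix(theta, N, n)
    theta_attr <- theta
    if (spec$family == "mixed_rasch") {
      cls <- rbinom(N, 1L, spec$class_prop)
      # effective difficulty beta + dif_shift for class members
      Th <- Th - outer(cls, items$dif_shift)
    }
  }
  p <- irf_prob(Th, items)
  X <- matrix(as.integer(matrix(runif(N * n), N, n) < p), N, n,
              dimnames = list(paste0("P", seq_len(N)), paste0("I", seq_len(n))))
  attr(X, "theta") <- theta_attr
  if (!is.null(cls)) attr(X, "latent_class") <- cls
  X
}

#' Impose surface local dependence on a response matrix
#'
#' Models a prerequisite relation between two items: among respondents who
#' solved the dependent item but not the prerequisite, the prerequisite
#' response is overwritten to 1 independently with probability
#' `overwrite_prob`.  All other entries are untouched.  In the study's
#' parameterization the prerequisite has difficulty -0.626 and the dependent
#' item 0.184, and the overwrite probability is 0.9 (major violation) or 0.8
#' (minor violation).
#'
#' @param X 0/1 response matrix generated under the Rasch model.
#' @param prereq_item,dependent_item distinct column indices.
#' @param overwrite_prob overwrite probability in (0, 1].
#' @return The altered matrix (attributes preserved).
#' @export
apply_surface_ld <- function(X, prereq_item = 1L, dependent_item = 2L,
                             overwrite_prob = 0.9) {
  at <- attributes(X)
  X <- as_response_matrix(X)
  attributes(X)[c("theta", "latent_class")] <-
    at[c("theta", "latent_class")]
  if (prereq_item == dependent_item)
    stop("prerequisite and dependent item must differ")
  if (overwrite_prob <= 0 || overwrite_prob > 1)
    stop("overwrite_prob must lie in (0, 1]")
  idx <- which(X[, dependent_item] == 1L & X[, prereq_item] == 0L)
  if (length(idx)) {
    flip <- idx[runif(length(idx)) < overwrite_prob]
    X[flip, prereq_item] <- 1L
  }
  X
}

# generate a dataset under a spec, including the surface-LD two-step
generate_dataset <- function(spec, N, items) {
  if (spec$family == "surface_ld") {
    X <- sim_responses(sim_spec("rasch"), N, items)
    apply_surface_ld(X, spec$prereq_item, spec$dependent_item,
                     spec$overwrite_prob)
  } else {
    sim_responses(spec, N, items)
  }
}
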