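test_that("item difficulty draws honor the seed contract and N(0,1) law", {
  set.seed(42)
  a <- draw_item_difficulties(10)
  set.seed(42)
  b <- draw_item_difficulties(10)
  expect_identical(a$beta, b$beta)
  expect_equal(a$alpha, rep(1, 10))
  expect_equal(a$gamma, rep(0, 10))
  set.seed(99)
  pooled <- replicate(10000, draw_item_difficulties(10)$beta)
  se_mean <- 1 / sqrt(length(pooled))
  expect_lt(abs(mean(pooled)), 3 * se_mean)
  expect_lt(abs(sd(pooled) - 1), 3 / sqrt(2 * length(pooled)))
  expect_error(draw_item_difficulties(1), "at least 2")
})

test_that("response probabilities follow the generalized item response function", {
  items <- rasch_items(beta = c(-1, 0, 1), gamma = c(0, 0.25, 0.25),
                       alpha = c(1, 1, 2))
  # lower asymptote at very low ability
  p_low <- irf_prob(rep(-20, 2), items)
  expect_equal(p_low[1, ], c(0, 0.25, 0.25), tolerance = 1e-6)
  # Rasch item: plain logistic
  expect_equal(irf_prob(0.5, items)[1, 1], plogis(0.5 - (-1)))
  # discrimination scales the logit
  expect_equal(irf_prob(2, items)[1, 3], 0.25 + 0.75 * plogis(2 * (2 - 1)))
})

test_that("degenerate violation parameters reproduce the Rasch null", {
  set.seed(3)
  items <- draw_item_difficulties(10)
  # 2PL with zero log-variance has alpha = 1: same stream, same data
  set.seed(11)
  x_rasch <- sim_responses(sim_spec("rasch"), 50, items)
  itm2 <- items
  set.seed(777); itm2$alpha <- rlnorm(10, 0, 0)
  set.seed(11)
  x_2pl <- sim_responses(sim_spec("twopl", log_var = 0), 50, itm2)
  expect_identical(unclass(x_rasch)[, ], unclass(x_2pl)[, ])
  # mixed Rasch with zero shift: identical stream apart from the class draw
  itm3 <- items; itm3$dif_shift <- rep(0, 10)
  set.seed(11)
  x_mix <- sim_responses(sim_spec("mixed_rasch"), 50, itm3)
  expect_equal(mean(x_mix), mean(x_rasch), tolerance = 0.15)
  # perfectly correlated traits collapse to one dimension
  set.seed(4)
  itm4 <- draw_condition_items(sim_spec("multidim", r = 1), 10)
  x_uni <- sim_responses(sim_spec("multidim", r = 1), 50, itm4)
  th <- attr(x_uni, "theta")
  expect_equal(th[, 1], th[, 2])
})

test_that("multidimensional generation draws correlated traits and splits items", {
  spec <- sim_spec("multidim", r = 0.7)
  set.seed(8)
  items <- draw_condition_items(spec, 10)
  expect_identical(items$dimension, rep(1:2, each = 5L))
  set.seed(9)
  X <- sim_responses(spec, 20000, items)
  th <- attr(X, "theta")
  expect_equal(cor(th[, 1], th[, 2]), 0.7, tolerance = 0.02)
  expect_error(sim_responses(spec, 10, draw_item_difficulties(9)),
               "even number|dimension")
  expect_error(draw_condition_items(spec, 9), "even number")
})

test_that("marginal item solve rates match quadrature of the response function", {
  # Gauss-Hermite integral of the IRF over N(0,1) vs Monte-Carlo margins
  gh <- pracma::gaussHermite(61)
  z <- sqrt(2) * gh$x; w <- gh$w / sqrt(pi)
  items <- rasch_items(beta = c(-0.626, 0.184, 1.2))
  expected <- colSums(w * plogis(outer(z, items$beta, "-")))
  set.seed(12)
  X <- sim_responses(sim_spec("rasch"), 2e5, items)
  mc_se <- sqrt(expected * (1 - expected) / nrow(X))
  expect_true(all(abs(colMeans(X) - expected) < 4 * mc_se))
  # the 0.184 item is solved by about 46% of a standard-normal population
  expect_equal(expected[2], 0.462, tolerance = 0.001)
})

test_that("surface local dependence only overwrites the targeted pattern", {
  set.seed(21)
  items <- rasch_items(beta = c(-0.626, 0.184, 0.5))
  X <- sim_responses(sim_spec("rasch"), 5000, items)
  Y <- apply_surface_ld(X, 1, 2, 0.9)
  expect_true(all(Y >= X))                       # never decreases
  changed <- which(rowSums(Y != X) > 0)
  expect_true(all(X[changed, 1] == 0 & X[changed, 2] == 1))
  expect_true(all(Y[changed, 1] == 1))
  expect_identical(X[, 3], Y[, 3])               # untouched column
  # complete overwrite leaves no (dependent = 1, prereq = 0) rows
  Z <- apply_surface_ld(X, 1, 2, 1)
  expect_identical(sum(Z[, 2] == 1 & Z[, 1] == 0), 0L)
  expect_error(apply_surface_ld(X, 2, 2, 0.9), "differ")
  expect_error(sim_responses(sim_spec("surface_ld"), 10, items), "post hoc")
})

test_that("mixed-Rasch class members see shifted difficulties", {
  spec <- sim_spec("mixed_rasch", dif_frac = 0.4)
  set.seed(31)
  items <- draw_condition_items(spec, 10)
  expect_equal(items$dif_shift, c(rep(-0.8, 4), rep(0, 6)))
  set.seed(32)
  X <- sim_responses(spec, 40000, items)
  cls <- attr(X, "latent_class")
  expect_equal(mean(cls), 0.4, tolerance = 0.02)
  # shifted items are easier for the shifted class, by about the logit shift
  in_cls <- colMeans(X[cls == 1, 1:4])
  out_cls <- colMeans(X[cls == 0, 1:4])
  expect_true(all(in_cls > out_cls))
  unshifted_gap <- colMeans(X[cls == 1, 5:10]) - colMeans(X[cls == 0, 5:10])
  expect_true(all(abs(unshifted_gap) < 0.03))
})

test_that("generating-model specs validate their parameter ranges", {
  expect_error(sim_spec("surface_ld", overwrite_prob = 1.2), "0, 1")
  expect_error(sim_spec("multidim", r = 1.5), "-1, 1")
  expect_error(sim_spec("guessing", gamma = 1), "0, 1")
  expect_error(sim_spec("twopl", log_var = -1), "nonnegative")
  expect_error(sim_spec("rasch", gamma = 0.2), "unknown parameter")
  spec <- sim_spec("twopl", log_var = 0.09)
  expect_equal(spec$log_var, 0.09)
})
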