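test_that("MML recovers difficulties and the latent sd from Rasch data", {
  set.seed(41)
  items <- draw_item_difficulties(10)
  X <- sim_responses(sim_spec("rasch"), 5000, items)
  fit <- rasch_mml(X)
  expect_true(fit$converged)
  expect_equal(fit$q, 11L)
  expect_lt(abs(fit$latent_sd - 1), 0.1)
  expect_lt(mean(abs(fit$beta_hat - items$beta)), 0.1)
})

test_that("the marginal log-likelihood never decreases across EM cycles", {
  d <- make_null_data(N = 300, n = 8, seed = 42)
  fit <- rasch_mml(d$X)
  expect_true(all(diff(fit$ll_trace) > -1e-7 * abs(fit$marg_loglik)))
})

test_that("estimation bias shrinks with the sample size", {
  set.seed(43)
  items <- draw_item_difficulties(8)
  mae <- vapply(c(300, 8000), function(N) {
    X <- sim_responses(sim_spec("rasch"), N, items)
    c(cml = mean(abs(rasch_cml(X)$beta_hat - (items$beta - mean(items$beta)))),
      mml = mean(abs(rasch_mml(X)$beta_hat - items$beta)))
  }, c(cml = 0, mml = 0))
  expect_lt(mae["cml", 2], mae["cml", 1])
  expect_lt(mae["mml", 2], mae["mml", 1])
})

test_that("model moments reduce to closed forms in limiting cases", {
  d <- make_null_data(N = 400, n = 6, seed = 44)
  fit <- rasch_mml(d$X)
  mom <- model_moments(fit, order = 2)
  # a vanishing latent sd factorizes the joint moments
  frozen <- fit
  frozen$latent_sd <- 1e-8
  m0 <- model_moments(frozen, order = 2)
  pairs <- combn(6, 2)
  expect_equal(unname(m0$pi2),
               unname(m0$pi1[pairs[1, ]] * m0$pi1[pairs[2, ]]),
               tolerance = 1e-6)
  # bounds: Frechet and monotonicity of joint moments
  expect_true(all(mom$pi2 <= pmin(mom$pi1[pairs[1, ]], mom$pi1[pairs[2, ]]) + 1e-12))
  expect_true(all(mom$pi2 >= pmax(0, mom$pi1[pairs[1, ]] + mom$pi1[pairs[2, ]] - 1) - 1e-12))
})

test_that("quadrature moments agree with large-sample Monte-Carlo integrals", {
  set.seed(45)
  items <- rasch_items(beta = c(0.184, -0.5, 0.9))
  X <- sim_responses(sim_spec("rasch"), 1500, items)
  fit <- rasch_mml(X)
  # an item of difficulty 0.184 under a standard-normal trait is solved by
  # about 46% of respondents
  gh <- raschgof:::gh_rule(61)
  p_true <- sum(gh$w * plogis(gh$z - 0.184))
  expect_equal(p_true, 0.462, tolerance = 0.001)
  theta <- rnorm(2e5) * fit$latent_sd
  mc <- colMeans(plogis(outer(theta, unname(fit$beta_hat), "-")))
  mom <- model_moments(fit, order = 1)
  mc_se <- sqrt(mc * (1 - mc) / length(theta)) * 2  # crude delta bound
  expect_true(all(abs(mom$pi1 - mc) < 4 * pmax(mc_se, 1e-4)))
  # fitted() exposes the univariate moments, close to the item means
  expect_equal(unname(fitted(fit)), unname(mom$pi1))
  expect_true(all(abs(fitted(fit) - colMeans(X)) < 0.05))
})

test_that("MML rejects constant columns and reports non-convergence structurally", {
  X <- cbind(rep(1L, 30), rbinom(30, 1, 0.5), rbinom(30, 1, 0.5))
  colnames(X) <- c("A", "B", "C")
  err <- tryCatch(rasch_mml(X), raschgof_degenerate = function(e) e)
  expect_s3_class(err, "raschgof_degenerate")
  expect_match(conditionMessage(err), "A")
  d <- make_null_data(N = 200, n = 6, seed = 46)
  err2 <- tryCatch(rasch_mml(d$X, max_cycles = 2L),
                   raschgof_nonconvergence = function(e) e)
  expect_s3_class(err2, "raschgof_nonconvergence")
  expect_named(err2$last, c("beta", "sigma", "ll_trace"))
})

test_that("simulate() round-trips the fitted model distribution", {
  set.seed(47)
  items <- draw_item_difficulties(6)
  X <- sim_responses(sim_spec("rasch"), 2000, items)
  fit <- rasch_mml(X)
  sims <- simulate(fit, nsim = 3, seed = 48, N = 2000)
  expect_length(sims, 3)
  avg <- Reduce(`+`, lapply(sims, colMeans)) / 3
  expect_true(all(abs(avg - fitted(fit)) < 0.04))
})
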