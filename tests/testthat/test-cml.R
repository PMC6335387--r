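test_that("elementary symmetric functions match enumeration and closed forms", {
  expect_equal(elementary_symmetric(c(1, 1)), c(1, 2, 1))
  expect_equal(elementary_symmetric(c(0.5, 1, 2))[3], 3.5)  # 0.5*1+0.5*2+1*2
  set.seed(5)
  for (n in c(5, 9, 12)) {
    eps <- exp(rnorm(n, sd = 1.2))
    got <- elementary_symmetric(eps)
    want <- esf_bruteforce(eps)
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(elementary_symmetric(c(1, -1)), "positive")
  expect_error(elementary_symmetric(c(1, 0)), "positive")
})

test_that("ESF derivatives equal the ESFs of the reduced parameter vector", {
  set.seed(6)
  eps <- exp(rnorm(7))
  d <- elementary_symmetric(eps, derivatives = TRUE)
  expect_equal(d$esf, esf_bruteforce(eps), tolerance = 1e-10)
  for (i in seq_along(eps)) {
    reduced <- esf_bruteforce(eps[-i])
    # d gamma_r / d eps_i is the order r-1 ESF without item i
    expect_equal(d$deriv[-1, i], reduced, tolerance = 1e-10)
    expect_equal(d$deriv[1, i], 0)
  }
})

test_that("two-item CML recovers the closed-form log-odds of the off-diagonal counts", {
  # conditional on raw score 1, P(pattern 10) = eps1 / (eps1 + eps2):
  # 30 persons with (1,0) and 10 with (0,1) give beta2 - beta1 = log 3
  X <- rbind(
    matrix(rep(c(1L, 0L), 30), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), 10), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 1L), 5), ncol = 2, byrow = TRUE),   # extreme, dropped
    matrix(rep(c(0L, 0L), 5), ncol = 2, byrow = TRUE)
  )
  fit <- rasch_cml(X)
  expect_equal(unname(diff(fit$beta_hat)), log(3), tolerance = 1e-7)
  expect_equal(sum(fit$beta_hat), 0, tolerance = 1e-10)
  expect_equal(fit$n_used, 40L)
  expect_equal(fit$n_dropped, 10L)
})

test_that("exchangeable item columns give all-zero difficulties", {
  base <- c(1L, 1L, 0L, 0L)
  X <- do.call(rbind, lapply(0:3, function(k)
    base[(seq_len(4) + k - 1) %% 4 + 1]))
  X <- X[rep(1:4, 5), ]
  fit <- rasch_cml(X)
  expect_equal(unname(fit$beta_hat), rep(0, 4), tolerance = 1e-8)
})

test_that("conditional log-likelihood matches the enumeration oracle and is shift-invariant", {
  d <- make_null_data(N = 80, n = 6, seed = 7)
  fit <- rasch_cml(d$X)
  expect_equal(fit$cond_loglik, cond_loglik_oracle(d$X, fit$beta_hat),
               tolerance = 1e-8)
  expect_lt(fit$cond_loglik, 0)
  # invariance under a location shift of all difficulties
  shifted <- cond_loglik_oracle(d$X, fit$beta_hat + 1.7)
  expect_equal(shifted, fit$cond_loglik, tolerance = 1e-8)
  # the sum-zero optimum beats nearby points
  set.seed(8)
  for (k in 1:5) {
    pert <- rnorm(6, sd = 0.1); pert <- pert - mean(pert)
    expect_lt(cond_loglik_oracle(d$X, fit$beta_hat + pert), fit$cond_loglik)
  }
})

test_that("CML estimates are invariant to person order and equivariant to item order", {
  d <- make_null_data(N = 150, n = 8, seed = 9)
  fit <- rasch_cml(d$X)
  set.seed(10)
  prow <- sample(nrow(d$X))
  pcol <- sample(ncol(d$X))
  expect_equal(rasch_cml(d$X[prow, ])$beta_hat, fit$beta_hat,
               tolerance = 1e-8)
  fit_c <- rasch_cml(d$X[, pcol])
  expect_equal(unname(fit_c$beta_hat), unname(fit$beta_hat[pcol]),
               tolerance = 1e-8)
})

test_that("CML difficulties are consistent under Rasch data", {
  set.seed(13)
  items <- draw_item_difficulties(10)
  X <- sim_responses(sim_spec("rasch"), 5000, items)
  fit <- rasch_cml(X)
  centered_truth <- items$beta - mean(items$beta)
  expect_lt(mean(abs(fit$beta_hat - centered_truth)), 0.1)
})

test_that("degenerate inputs raise structured errors naming the items", {
  set.seed(14)
  X <- cbind(I1 = rep(1L, 20), I2 = rbinom(20, 1, 0.5), I3 = rbinom(20, 1, 0.5))
  X[1, ] <- c(1L, 1L, 0L)  # keep at least one non-extreme person
  err <- tryCatch(rasch_cml(X), raschgof_degenerate = function(e) e)
  expect_s3_class(err, "raschgof_degenerate")
  expect_true(1L %in% err$items)
  expect_match(conditionMessage(err), "I1")
  all_extreme <- rbind(rep(1L, 3), rep(0L, 3))
  expect_error(rasch_cml(all_extreme), "extreme")
})
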