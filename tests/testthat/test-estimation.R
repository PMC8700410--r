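test_that("log-likelihood and analytic score match independent evaluations", {
  x <- fixture_sample()
  expect_equal(neitl_loglik(2, 1, x), sum(dneitl(x, 2, 1, log = TRUE)),
               tolerance = 1e-12)
  expect_equal(neitl_loglik(2, 1, x[1]), dneitl(x[1], 2, 1, log = TRUE))
  # central differences reproduce the analytic gradient
  num_grad <- function(theta, delta, x, h = 1e-6) {
    c((neitl_loglik(theta + h, delta, x) -
         neitl_loglik(theta - h, delta, x)) / (2 * h),
      (neitl_loglik(theta, delta + h, x) -
         neitl_loglik(theta, delta - h, x)) / (2 * h))
  }
  for (p in list(c(2, 1), c(0.5, 0.5), c(4, 2.5))) {
    expect_equal(unname(neitl_score(p[1], p[2], x)), num_grad(p[1], p[2], x),
                 tolerance = 1e-5)
  }
  # single-observation toy sample
  expect_equal(unname(neitl_score(1.5, 2, 0.8)), num_grad(1.5, 2, 0.8),
               tolerance = 1e-5)
  expect_error(neitl_loglik(-1, 1, x), "positive")
})

test_that("maximum likelihood recovers parameters and zeroes the score", {
  x <- rneitl(5000, 3, 3, seed = 21)
  fit <- neitl_fit(x)
  expect_s3_class(fit, "neitl_fit")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$gradient)), 1e-3)
  expect_lt(abs(fit$estimate["theta"] - 3), 3 * fit$se["theta"])
  expect_lt(abs(fit$estimate["delta"] - 3), 3 * fit$se["delta"])
  # permutation invariance
  fit2 <- neitl_fit(sample(x), starts = matrix(log(c(3, 3)), 1))
  expect_equal(unname(fit2$estimate), unname(fit$estimate),
               tolerance = 1e-4)
  # accessors
  expect_equal(unname(coef(fit)), unname(fit$estimate))
  expect_equal(stats::AIC(fit), 4 - 2 * fit$loglik)
  expect_equal(stats::BIC(fit), 2 * log(5000) - 2 * fit$loglik)
  expect_length(simulate(fit, nsim = 10, seed = 1), 10)
  expect_error(neitl_fit(c(1, -2, 3)), "positive")
})

test_that("spacing objective satisfies its closed-form properties", {
  # n = 1: objective (log F + log(1-F))/2, maximal at the median
  med <- qneitl(0.5, 2, 2)
  obj_med <- mps_objective(2, 2, med)
  expect_equal(obj_med, log(0.5))
  expect_gt(obj_med, mps_objective(2, 2, qneitl(0.3, 2, 2)))
  # AM-GM bound: mean log spacing <= log(1/(n+1))
  x <- fixture_sample(40)
  expect_lte(mps_objective(2, 1, x), log(1 / (length(x) + 1)))
  # permutation invariance of the objective
  expect_equal(mps_objective(1.3, 0.9, x), mps_objective(1.3, 0.9, rev(x)))
  # exact ties fall back to the density term and stay finite
  xt <- c(0.5, 1.07, 1.07, 2.3)
  expect_true(is.finite(mps_objective(1, 1, xt)))
  tied_term <- dneitl(1.07, 1, 1, log = TRUE)
  untied <- c(0, pneitl(sort(xt), 1, 1), 1)
  manual <- mean(c(log(diff(untied))[-3], tied_term))
  expect_equal(mps_objective(1, 1, xt), manual)
})

test_that("MPS and ML agree on large samples", {
  x <- rneitl(2000, 2, 2, seed = 33)
  st <- matrix(log(c(2, 2)), 1)
  fm <- neitl_fit(x, search = "local", starts = st)
  fp <- neitl_fit(x, method = "mps", search = "local", starts = st)
  expect_lt(abs(fm$estimate["theta"] - fp$estimate["theta"]),
            2 * fm$se["theta"])
  expect_lt(abs(fm$estimate["delta"] - fp$estimate["delta"]),
            2 * fm$se["delta"])
})

test_that("posterior machinery is coherent", {
  x <- fixture_sample(50)
  # nearly flat prior: log posterior - log likelihood is constant
  pr <- neitl_prior(1, 1e-8, 1, 1e-8)
  d1 <- neitl_log_posterior(0.7, 1.2, x, pr) - neitl_loglik(0.7, 1.2, x)
  d2 <- neitl_log_posterior(3, 0.4, x, pr) - neitl_loglik(3, 0.4, x)
  expect_equal(d1, d2, tolerance = 1e-6)
  # prior-only sampling recovers the gamma prior moments
  pd <- prior_draws(neitl_prior(2, 1, 3, 2), mcmc_control(20000, 2000),
                    seed = 5)
  expect_equal(mean(pd$draws$theta), 2, tolerance = 0.1)
  expect_equal(mean(pd$draws$delta), 1.5, tolerance = 0.08)
  expect_equal(stats::var(pd$draws$theta), 2, tolerance = 0.25)
  # determinism under a seed
  b1 <- neitl_fit(x, method = "bayes", mcmc = mcmc_control(1500, 300),
                  seed = 9)
  b2 <- neitl_fit(x, method = "bayes", mcmc = mcmc_control(1500, 300),
                  seed = 9)
  expect_identical(b1$draws, b2$draws)
  expect_true(all(b1$acc_rate > 0 & b1$acc_rate < 1))
  expect_error(mcmc_control(100, 200), "smaller")
})

test_that("Bayes with a weak prior tracks the MLE on a large sample", {
  x <- rneitl(1000, 2, 2, seed = 13)
  fm <- neitl_fit(x, search = "local", starts = matrix(log(c(2, 2)), 1))
  fb <- neitl_fit(x, method = "bayes", prior = neitl_prior(1, .01, 1, .01),
                  mcmc = mcmc_control(4000, 1000), seed = 3)
  expect_lt(abs(fb$estimate["theta"] - fm$estimate["theta"]),
            fm$se["theta"])
  expect_lt(abs(fb$estimate["delta"] - fm$estimate["delta"]),
            fm$se["delta"])
  # credible interval covers the posterior mean
  ci <- confint(fb)
  expect_true(all(ci[, "lower"] < fb$estimate & fb$estimate < ci[, "upper"]))
})

test_that("interval estimates have the stated structure", {
  fit <- neitl_fit(fixture_sample(80))
  ci <- confint(fit, level = 0.95)
  z <- stats::qnorm(0.975)
  expect_equal(unname(ci[, "upper"] - ci[, "lower"]), unname(2 * z * fit$se),
               tolerance = 1e-10)
  # 2 * 1.95996 per unit standard error
  expect_equal(2 * z, 3.9199, tolerance = 1e-4)
  # bootstrap: intervals widen with the level, deterministic under a seed
  x <- fixture_sample(50)
  st <- matrix(log(c(2, 1)), 1)
  b90 <- bootstrap_ci(x, B = 100, level = 0.90, seed = 4, starts = st)
  b99 <- bootstrap_ci(x, B = 100, level = 0.99, seed = 4, starts = st)
  expect_true(all(b99$ci[, "upper"] - b99$ci[, "lower"] >=
                    b90$ci[, "upper"] - b90$ci[, "lower"]))
  expect_true(all(b90$ci[, "lower"] <= b90$ci[, "upper"]))
  expect_error(bootstrap_ci(x, B = 50), "at least 100")
})

test_that("plug-in survival/hazard report satisfies identities", {
  fit <- neitl_fit(fixture_sample(80))
  rel <- reliability_at(fit, c(0.25, 0.35))
  est <- fit$estimate
  expect_equal(rel$R, pneitl(c(0.25, 0.35), est[1], est[2],
                             lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(rel$H, hneitl(c(0.25, 0.35), est[1], est[2]),
               tolerance = 1e-12)
  expect_true(all(rel$R_lower <= rel$R & rel$R <= rel$R_upper))
  expect_true(all(rel$H_lower <= rel$H & rel$H <= rel$H_upper))
  # delta-method and bootstrap R intervals agree in scale on a larger sample
  x <- rneitl(400, 2, 2, seed = 17)
  f2 <- neitl_fit(x, search = "local", starts = matrix(log(c(2, 2)), 1))
  r2 <- reliability_at(f2, 0.25)
  expect_lt(r2$R_upper - r2$R_lower, 0.2)
  expect_error(reliability_at(fit, -1), "positive")
})
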