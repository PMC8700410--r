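test_that("a single replicate reduces to the direct computation", {
  s <- mc_study(0.5, 3, n = 30, methods = "mle", n_rep = 1, seed = 5)
  df <- as.data.frame(s)
  # reproduce the replicate by hand: same seed, same draw, same local fit
  x <- rneitl(30, 0.5, 3, seed = 5)
  fit <- neitl_fit(x, search = "local", starts = matrix(log(c(0.5, 3)), 1))
  expect_equal(df$mean_est[df$quantity == "theta"],
               unname(fit$estimate["theta"]), tolerance = 1e-10)
  expect_equal(df$mean_est[df$quantity == "delta"],
               unname(fit$estimate["delta"]), tolerance = 1e-10)
  # survival rows evaluate at the true quantiles, so truth is 1 - level
  expect_equal(df$true[df$quantity == "R1"], 0.75)
  expect_equal(df$true[df$quantity == "R2"], 0.65)
  expect_equal(df$MSE, (df$mean_est - df$true)^2, tolerance = 1e-12)
})

test_that("study summaries are deterministic and internally consistent", {
  s1 <- mc_study(0.5, 0.5, n = c(30, 60), methods = "mle", n_rep = 60,
                 seed = 8)
  s2 <- mc_study(0.5, 0.5, n = c(30, 60), methods = "mle", n_rep = 60,
                 seed = 8)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  df <- as.data.frame(s1)
  # bias^2 cannot exceed MSE beyond Monte Carlo error
  expect_true(all(df$AE^2 <= df$MSE + 3 * df$MSE_mcse))
  expect_true(all(df$MSE >= 0) && all(df$L.CI > 0))
})

test_that("doubling the replication shrinks the MSE Monte Carlo error", {
  a <- mc_study(0.5, 0.5, n = 30, methods = "mle", n_rep = 100, seed = 14)
  b <- mc_study(0.5, 0.5, n = 30, methods = "mle", n_rep = 400, seed = 14)
  ma <- as.data.frame(a); mb <- as.data.frame(b)
  ratio <- ma$MSE_mcse[ma$quantity == "R1"] /
    mb$MSE_mcse[mb$quantity == "R1"]
  # quadrupling replicates should halve the Monte Carlo standard error
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.5)
})

test_that("stress-strength study tracks the true reliability across sizes", {
  s <- mc_ss_study(0.6, 0.75, 0.65, 2.5,
                   nm = rbind(c(25, 30), c(80, 70), c(150, 120)),
                   methods = "mle", n_rep = 100, seed = 42)
  df <- as.data.frame(s)
  r <- df[df$quantity == "R", ]
  expect_equal(nrow(r), 3)
  truth <- ss_reliability(0.6, 0.75, 0.65, 2.5)
  expect_equal(r$true, rep(truth, 3))
  expect_true(all(abs(r$AE) < 0.05))
  # MSE of R-hat decreases as both samples grow
  expect_true(all(diff(r$MSE) < 0))
  expect_true(all(diff(r$L.CI) < 0))
})

test_that("wide tables round-trip through CSV and handle empty input", {
  s <- mc_study(0.5, 3, n = 30, methods = "mle", n_rep = 5, seed = 2)
  tab <- format_sim_table(s, digits = 6)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back$MSE.mle, tab$MSE.mle)
  expect_equal(back$quantity, tab$quantity)
  empty <- format_sim_table(as.data.frame(s)[0, ])
  expect_equal(nrow(empty), 0)
})
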