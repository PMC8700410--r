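test_that("raw moments behave like moments", {
  expect_equal(neitl_moment(0, 3, 2), 1)
  # nonexistent moment (tail index theta*delta + 1) is refused
  expect_error(neitl_moment(2, 0.5, 1), "does not exist")
  # a large simulated sample reproduces the quadrature mean and variance
  m <- neitl_moments(3, 2)
  z <- rneitl(1e6, 3, 2, seed = 5)
  se_mean <- stats::sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - m$mean), 3 * se_mean)
  se_var <- stats::sd((z - mean(z))^2) / sqrt(length(z))
  expect_lt(abs(stats::var(z) - m$variance), 3 * se_var)
  # beta-series form at its terminating point
  expect_equal(neitl_moment_series(1, 1, 4), neitl_moment(1, 1, 4),
               tolerance = 1e-5)
  expect_equal(neitl_moment_series(2, 1, 4), neitl_moment(2, 1, 4),
               tolerance = 1e-5)
  expect_error(neitl_moment_series(2, 1, 1.5), "delta > r")
})

test_that("incomplete moments and inequality curves are coherent", {
  # eta_r(y) recovers the full moment as y grows
  expect_equal(neitl_incomplete_moment(1, 1e6, 3, 3),
               neitl_moment(1, 3, 3), tolerance = 1e-6)
  # F(median) = 0.5 through the quantile function
  med <- qneitl(0.5, 3, 3)
  expect_equal(pneitl(med, 3, 3), 0.5, tolerance = 1e-12)
  # Lorenz dominance Lz(m) <= F(m), both in [0, 1], Lz nondecreasing
  ms <- c(0.2, 0.5, 0.739, 1.5, 4)
  lz <- vapply(ms, neitl_lorenz, numeric(1), theta = 3, delta = 2)
  Fm <- pneitl(ms, 3, 2)
  expect_true(all(lz >= 0 & lz <= 1))
  expect_true(all(lz <= Fm + 1e-12))
  expect_true(all(diff(lz) > 0))
  expect_equal(neitl_lorenz(1e7, 3, 2), 1, tolerance = 1e-4)
  bu <- neitl_bonferroni(0.739, 3, 2)
  expect_equal(bu, neitl_lorenz(0.739, 3, 2) / pneitl(0.739, 3, 2))
  expect_error(neitl_bonferroni(1e-300, 3, 2), "undefined")
})

test_that("quantile shape measures behave as quantile ratios", {
  sk <- bowley_skewness(2, 3)
  ku <- moors_kurtosis(2, 3)
  expect_true(is.finite(sk) && is.finite(ku))
  expect_gt(sk, 0)  # right-skewed
  # Bowley skewness is invariant under rescaling of the quantiles
  q <- qneitl(c(0.25, 0.5, 0.75), 2, 3)
  bow <- function(q) (q[3] - 2 * q[2] + q[1]) / (q[3] - q[1])
  expect_equal(bow(q), bow(10 * q), tolerance = 1e-12)
  # equidistant quartiles give zero Bowley skewness
  expect_equal(bow(c(1, 2, 3)), 0)
})

test_that("entropies are consistent across orders and routes", {
  # b -> 1 limit approaches the Shannon entropy from both sides
  sh <- shannon_entropy(3, 3)
  expect_equal(renyi_entropy(3, 3, 1 + 1e-3), sh, tolerance = 1e-2)
  expect_equal(renyi_entropy(3, 3, 1 - 1e-3), sh, tolerance = 1e-2)
  # Renyi entropy is nonincreasing in the order
  bs <- c(0.5, 0.8, 1.5, 2, 3)
  vals <- vapply(bs, function(b) renyi_entropy(3, 3, b), numeric(1))
  expect_true(all(diff(vals) < 0))
  # series form at its terminating point
  for (b in c(1.5, 2, 3)) {
    expect_equal(renyi_entropy_series(1, 3, b), renyi_entropy(1, 3, b),
                 tolerance = 1e-4)
  }
  # rho entropy shares the same f^rho integral as the Renyi entropy
  rho <- 2
  I <- exp((1 - rho) * renyi_entropy(1.5, 1, rho))
  expect_equal(rho_entropy(1.5, 1, rho), log1p(-I) / (rho - 1),
               tolerance = 1e-8)
  expect_error(rho_entropy(3, 3, 1), "differ from 1")
  # peaked density: int f^2 > 1 makes the rho entropy undefined
  expect_error(rho_entropy(5, 5, 2), "undefined")
})
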