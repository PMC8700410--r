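# Moments, incomplete moments, inequality curves, quantile shape measures
# and entropies of the NEITL distribution.
#
# The production path for every integral quantity is adaptive quadrature of
# the closed-form density; the series forms in series.R are cross-checks.
# The right tail of the density behaves like x^-(theta*delta + 2), so the
# r-th moment exists iff r < theta*delta + 1; this analytic existence check
# guards the quadrature.

.moment_exists <- function(r, theta, delta) r < theta * delta + 1

#' Raw moments of the NEITL distribution
#'
#' Computes `E[X^r]` by adaptive quadrature of `x^r * f(x)`.  The moment
#' exists iff `r < theta*delta + 1` (tail index of the density);
#' nonexistent moments are signalled as errors.
#'
#' @param r non-negative moment order.
#' @param theta,delta positive shape parameters.
#' @param rel.tol relative accuracy requested from [stats::integrate()].
#' @return the value of the r-th raw moment.
#' @examples
#' neitl_moment(1, theta = 3, delta = 2)  # 0.739
#' @export
neitl_moment <- function(r, theta, delta, rel.tol = 1e-10) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  if (r < 0) stop("'r' must be non-negative", call. = FALSE)
  if (r == 0) return(1)
  if (!.moment_exists(r, theta, delta)) {
    stop("moment of order ", r, " does not exist for theta*delta = ",
         format(theta * delta), " (requires r < theta*delta + 1)",
         call. = FALSE)
  }
  stats::integrate(function(x) x^r * dneitl(x, theta, delta), 0, Inf,
                   rel.tol = rel.tol)$value
}

#' Moment summary of the NEITL distribution
#'
#' Mean, variance, moment skewness and moment kurtosis from the first four
#' raw moments computed by quadrature.  Kurtosis is reported both raw
#' (`mu4 / sigma^4`) and as excess (`raw - 3`).
#'
#' @inheritParams neitl_moment
#' @return an object of class `neitl_moments`: a list with components
#'   `mean`, `variance`, `skewness`, `kurtosis` (raw), `excess_kurtosis`,
#'   and `raw` (the first four raw moments).
#' @examples
#' neitl_moments(theta = 3, delta = 2)
#' @export
neitl_moments <- function(theta, delta) {
  m <- vapply(1:4, neitl_moment, numeric(1), theta = theta, delta = delta)
  v <- m[2] - m[1]^2
  mu3 <- m[3] - 3 * m[1] * m[2] + 2 * m[1]^3
  mu4 <- m[4] - 4 * m[1] * m[3] + 6 * m[1]^2 * m[2] - 3 * m[1]^4
  structure(list(mean = m[1], variance = v,
                 skewness = mu3 / v^1.5,
                 kurtosis = mu4 / v^2,
                 excess_kurtosis = mu4 / v^2 - 3,
                 raw = m, theta = theta, delta = delta),
            class = "neitl_moments")
}

#' @export
print.neitl_moments <- function(x, digits = 4, ...) {
  cat("NEITL moment summary (theta =", format(x$theta),
      ", delta =", format(x$delta), ")\n")
  print(round(c(mean = x$mean, variance = x$variance,
                skewness = x$skewness, kurtosis = x$kurtosis), digits))
  invisible(x)
}

#' Incomplete moments and inequality curves
#'
#' `neitl_incomplete_moment` computes the r-th incomplete moment
#' `eta_r(y) = int_0^y x^r f(x) dx` by quadrature.  `neitl_lorenz` and
#' `neitl_bonferroni` are the Lorenz curve `Lz(m) = eta_1(m) / mean` and
#' Bonferroni curve `Bu(m) = Lz(m) / F(m)` built on the first incomplete
#' moment.
#'
#' @param r non-negative moment order.
#' @param y,m positive truncation point.
#' @param theta,delta positive shape parameters.
#' @return a single numeric value.
#' @export
neitl_incomplete_moment <- function(r, y, theta, delta) {
  .check_pos_scalar(y, "y")
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  # integrate on the probability scale: int_0^y x^r f dx = int_0^F(y) Q(u)^r du.
  # The bounded u-interval keeps adaptive quadrature reliable even when y is
  # far beyond the bulk of the distribution (where integrating x^r f over
  # (0, y) directly can miss the mass entirely).
  Fy <- pneitl(y, theta, delta)
  if (Fy == 0) return(0)
  stats::integrate(function(u) qneitl(u, theta, delta)^r, 0, Fy,
                   rel.tol = 1e-10)$value
}

#' @rdname neitl_incomplete_moment
#' @export
neitl_lorenz <- function(m, theta, delta) {
  neitl_incomplete_moment(1, m, theta, delta) / neitl_moment(1, theta, delta)
}

#' @rdname neitl_incomplete_moment
#' @export
neitl_bonferroni <- function(m, theta, delta) {
  Fm <- pneitl(m, theta, delta)
  if (Fm == 0) stop("F(m) = 0: Bonferroni curve undefined at m = ",
                    format(m), call. = FALSE)
  neitl_lorenz(m, theta, delta) / Fm
}

#' Quantile-based shape measures
#'
#' Bowley's quartile skewness
#' `(Q(3/4) - 2 Q(1/2) + Q(1/4)) / (Q(3/4) - Q(1/4))` and Moors' octile
#' kurtosis
#' `(Q(7/8) - Q(5/8) - Q(3/8) + Q(1/8)) / (Q(3/4) - Q(1/4))`
#' of the NEITL distribution, computed from the analytic quantile function.
#'
#' @param theta,delta positive shape parameters.
#' @return a single numeric value.
#' @export
bowley_skewness <- function(theta, delta) {
  q <- qneitl(c(0.25, 0.5, 0.75), theta, delta)
  (q[3] - 2 * q[2] + q[1]) / (q[3] - q[1])
}

#' @rdname bowley_skewness
#' @export
moors_kurtosis <- function(theta, delta) {
  q <- qneitl(c(1, 2, 3, 5, 6, 7) / 8, theta, delta)
  (q[6] - q[4] - q[2] + q[1]) / (q[5] - q[3])
}

# int f^b dx by quadrature, with a divergence check near the origin
.f_power_integral <- function(theta, delta, b) {
  out <- tryCatch(
    stats::integrate(function(x) dneitl(x, theta, delta)^b, 0, Inf,
                     rel.tol = 1e-9),
    error = function(e) stop("integral of f^", format(b),
                             " did not converge: ", conditionMessage(e),
                             call. = FALSE))
  out$value
}

#' Renyi and rho entropies of the NEITL distribution
#'
#' `renyi_entropy` computes `(1/(1-b)) log int f^b dx` by quadrature of the
#' closed-form density (the series of [renyi_entropy_series()] is the
#' cross-check).  `rho_entropy` computes
#' `(1/(rho-1)) log(1 - int f^rho dx)`, which shares the same integral; it
#' is only defined when `int f^rho < 1`, and an error is signalled
#' otherwise.
#'
#' @param theta,delta positive shape parameters.
#' @param b,rho entropy order, positive and not equal to 1.
#' @return a single numeric value.
#' @export
renyi_entropy <- function(theta, delta, b) {
  .check_pos_scalar(b, "b")
  if (b == 1) stop("'b' must differ from 1", call. = FALSE)
  (1 / (1 - b)) * log(.f_power_integral(theta, delta, b))
}

#' @rdname renyi_entropy
#' @export
rho_entropy <- function(theta, delta, rho) {
  .check_pos_scalar(rho, "rho")
  if (rho == 1) stop("'rho' must differ from 1", call. = FALSE)
  I <- .f_power_integral(theta, delta, rho)
  if (I >= 1) {
    stop("rho entropy undefined: int f^rho = ", format(I), " >= 1",
         call. = FALSE)
  }
  (1 / (rho - 1)) * log1p(-I)
}

#' Differential (Shannon) entropy of the NEITL distribution
#'
#' `-int f log f`, the `b -> 1` limit of the Renyi entropy; computed by
#' quadrature.
#'
#' @param theta,delta positive shape parameters.
#' @return a single numeric value.
#' @export
shannon_entropy <- function(theta, delta) {
  stats::integrate(function(x) {
    lf <- dneitl(x, theta, delta, log = TRUE)
    ifelse(is.finite(lf), -exp(lf) * lf, 0)
  }, 0, Inf, rel.tol = 1e-9)$value
}
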