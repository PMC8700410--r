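# Core distribution functions for the inverted Topp-Leone (ITL) baseline and
# the two-parameter NEITL distribution obtained from it through the
# new exponential-X (NE-X) family transform.
#
# All evaluations go through log-space intermediates: the baseline ratio
#   A(x; delta) = (1+2x)^delta / (1+x)^(2*delta)  in (0, 1]
# is only ever formed as exp(delta*log1p(2x) - 2*delta*log1p(x)), so that
# very large shape parameters (theta ~ 60 occurs in real fits) do not
# overflow, and complements such as 1 - G^2 = A*(2 - A) are computed
# without cancellation.

.check_pos_scalar <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0) {
    stop("'", name, "' must be a single positive finite number", call. = FALSE)
  }
  invisible(value)
}

.check_x <- function(x) {
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (any(!is.na(x) & x < 0)) {
    stop("negative values are outside the support (0, Inf)", call. = FALSE)
  }
  invisible(x)
}

# log A(x; delta); A is the ITL survival ratio, log A <= 0 for x >= 0
.log_A <- function(x, delta) delta * log1p(2 * x) - 2 * delta * log1p(x)

# Shared intermediates for the NEITL formulas at parameters (theta, delta):
#   la      = log A
#   A       = A(x; delta)
#   G       = ITL cdf = 1 - A
#   l1mG2   = log(1 - G^2) = log A + log(2 - A)
#   lD      = log(1 - (1-theta) G^2) = log(theta + (1-theta) A (2-A))
.neitl_parts <- function(x, theta, delta) {
  la <- .log_A(x, delta)
  A <- exp(la)
  list(la = la, A = A, G = -expm1(la),
       l1mG2 = la + log(2 - A),
       lD = log(theta + (1 - theta) * A * (2 - A)))
}

#' The inverted Topp-Leone distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the one-parameter inverted Topp-Leone (ITL) distribution with shape
#' `delta`, the baseline of the NEITL family.  Its CDF is
#' \deqn{G(x;\delta) = 1 - (1+2x)^\delta / (1+x)^{2\delta}, \quad x \ge 0.}
#'
#' @param x,q vector of non-negative quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations.
#' @param delta positive shape parameter.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `FALSE`, the survival function is returned.
#' @return `ditl` gives the density, `pitl` the distribution function,
#'   `qitl` the quantile function and `ritl` a random sample.
#' @examples
#' pitl(1, delta = 1)   # 1 - 3/4 = 0.25
#' qitl(pitl(2, 2), 2)  # 2
#' @export
ditl <- function(x, delta, log = FALSE) {
  .check_pos_scalar(delta, "delta")
  .check_x(x)
  ld <- log(2) + log(delta) + log(x) + (delta - 1) * log1p(2 * x) -
    (2 * delta + 1) * log1p(x)
  ld[x == 0] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname ditl
#' @export
pitl <- function(q, delta, lower.tail = TRUE, log.p = FALSE) {
  .check_pos_scalar(delta, "delta")
  .check_x(q)
  la <- .log_A(q, delta)
  if (lower.tail) {
    p <- -expm1(la)
    if (log.p) log(p) else p
  } else {
    if (log.p) la else exp(la)
  }
}

#' @rdname ditl
#' @export
qitl <- function(p, delta) {
  .check_pos_scalar(delta, "delta")
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)",
                                 call. = FALSE)
  # invert A(x) = (1-p): s = (1-p)^(1/delta) = (1+2x)/(1+x)^2, a quadratic in
  # x with discriminant 4(1-s); the positive root is taken
  s <- exp(log1p(-p) / delta)
  ((1 - s) + sqrt(1 - s)) / s
}

#' @rdname ditl
#' @export
ritl <- function(n, delta) {
  qitl(stats::runif(n), delta)
}

#' NE-X family CDF transform
#'
#' Applies the new exponential-X family map to a baseline CDF value `g`,
#' \deqn{F = 1 - \left[\frac{1-g^2}{1-(1-\theta)g^2}\right]^\theta,}
#' which adds the shape parameter `theta` to any baseline distribution.
#' With `theta = 1` the transform collapses to `g^2`.
#'
#' @param g baseline CDF values in \[0, 1\].
#' @param theta positive family shape parameter.
#' @return transformed CDF values in \[0, 1\].
#' @examples
#' nex_cdf(0.5, theta = 1)  # 0.25
#' @export
nex_cdf <- function(g, theta) {
  .check_pos_scalar(theta, "theta")
  if (any(!is.na(g) & (g < 0 | g > 1))) {
    stop("'g' must be a probability in [0, 1]", call. = FALSE)
  }
  g2 <- g * g
  -expm1(theta * (log1p(-g2) - log1p(-(1 - theta) * g2)))
}

#' The new exponential inverted Topp-Leone distribution
#'
#' Density, distribution function, survival function, hazard function,
#' quantile function and random generation for the NEITL distribution with
#' shape parameters `theta` (NE-X family shape) and `delta` (ITL baseline
#' shape).  The CDF is the NE-X transform of the ITL CDF,
#' \deqn{F(x) = 1 - \left[\frac{1-G(x)^2}{1-(1-\theta)G(x)^2}\right]^\theta,
#'   \quad G(x) = 1 - \frac{(1+2x)^\delta}{(1+x)^{2\delta}}.}
#' The support is (0, Inf); `dneitl` and `pneitl` return 0 at `x = 0`.
#'
#' @param x,q vector of non-negative quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations.
#' @param theta,delta positive shape parameters.
#' @param log,log.p logical; return values on the log scale.
#' @param lower.tail logical; if `FALSE` the survival function is returned
#'   (computed directly in log space, not as `1 - F`).
#' @param seed optional integer; when supplied, `rneitl` draws with a local
#'   RNG state seeded to `seed` and restores the caller's RNG afterwards, so
#'   the call is reproducible without global side effects.
#' @return numeric vector.
#' @examples
#' pneitl(1, theta = 1, delta = 1)          # pitl(1, 1)^2 = 0.0625
#' qneitl(pneitl(0.7, 3, 2), 3, 2)          # 0.7
#' hneitl(0.25, 3, 0.5)                     # hazard at t = 0.25
#' @export
dneitl <- function(x, theta, delta, log = FALSE) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  .check_x(x)
  pt <- .neitl_parts(x, theta, delta)
  lf <- log(4) + 2 * log(theta) + log(delta) + log(x) +
    (delta - 1) * log1p(2 * x) - (2 * delta + 1) * log1p(x) +
    log(pt$G) + (theta - 1) * pt$l1mG2 - (theta + 1) * pt$lD
  lf[x == 0] <- -Inf
  if (log) lf else exp(lf)
}

#' @rdname dneitl
#' @export
pneitl <- function(q, theta, delta, lower.tail = TRUE, log.p = FALSE) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  .check_x(q)
  pt <- .neitl_parts(q, theta, delta)
  lsf <- theta * (pt$l1mG2 - pt$lD)   # log survival
  if (lower.tail) {
    p <- -expm1(lsf)
    if (log.p) log(p) else p
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname dneitl
#' @export
hneitl <- function(x, theta, delta) {
  lsf <- pneitl(x, theta, delta, lower.tail = FALSE, log.p = TRUE)
  if (any(lsf == -Inf)) {
    stop("survival function underflows to 0; hazard not representable there",
         call. = FALSE)
  }
  exp(dneitl(x, theta, delta, log = TRUE) - lsf)
}

#' @rdname dneitl
#' @export
qneitl <- function(p, theta, delta) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)",
                                 call. = FALSE)
  # analytic inversion chain: t = (1-p)^(1/theta),
  # G^2 = (1-t)/(1 - t(1-theta)), then invert the ITL CDF at G
  t <- exp(log1p(-p) / theta)
  g2 <- (1 - t) / (1 - t * (1 - theta))
  qitl(sqrt(g2), delta)
}

#' @rdname dneitl
#' @export
rneitl <- function(n, theta, delta, seed = NULL) {
  draw <- function() qneitl(stats::runif(n), theta, delta)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state on exit.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
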