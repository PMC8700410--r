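# Truncated series expansions of the NEITL CDF, PDF, moments, Renyi entropy
# and common-theta stress-strength reliability.
#
# These series arise from the generalized binomial expansions
#   (1 - z)^(-k)  = sum_i choose(i+k-1, i) z^i,          z = (1-theta) G^2,
#   (1 - w)^v    = sum_j choose(v, j) (-w)^j,            w = G^2,
# and converge where |(1-theta) G^2| < 1; coefficient sums taken over the
# whole support require |1 - theta| < 1, i.e. theta in (0, 2).  They are
# retained purely as independent cross-checks of the closed-form evaluators
# and of the quadrature paths; the closed forms are always the production
# route.

#' Truncation settings for series cross-checks
#'
#' @param max_terms maximum number of terms per expansion index.
#' @param tol absolute tail tolerance at which a sum is truncated.
#' @return a list with class `series_config`.
#' @export
series_config <- function(max_terms = 200L, tol = 1e-10) {
  if (!is.numeric(max_terms) || length(max_terms) != 1L || max_terms < 1) {
    stop("'max_terms' must be a positive integer", call. = FALSE)
  }
  .check_pos_scalar(tol, "tol")
  structure(list(max_terms = as.integer(max_terms), tol = tol),
            class = "series_config")
}

# generalized binomial coefficient choose(a + i - 1, i) for real a > 0,
# i.e. the negative-binomial expansion weight of (1-z)^(-a)
.nb_coef <- function(a, i) exp(lgamma(a + i) - lgamma(a) - lfactorial(i))

#' Series expansions of the NEITL CDF and PDF
#'
#' Evaluate the NEITL distribution and density functions through their
#' mixture representations as infinite linear combinations of powers of the
#' baseline ITL CDF.  Used only as oracles against [pneitl()] / [dneitl()];
#' convergence of the coefficient sums on the whole support requires
#' `theta` in (0, 2).
#'
#' @param x non-negative quantiles.
#' @param theta,delta positive shape parameters.
#' @param cfg a [series_config()].
#' @return numeric vector of CDF (or density) values.
#' @export
pneitl_series <- function(x, theta, delta, cfg = series_config()) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  .check_x(x)
  G2 <- pitl(x, delta)^2
  # F = 1 - sum_i nb(theta,i) (1-theta)^i G^(2i) * sum_j choose(theta,j)(-1)^j G^(2j)
  s <- 0
  j <- seq_len(cfg$max_terms + 1L) - 1L
  inner <- drop(outer(G2, j, `^`) %*% (choose(theta, j) * (-1)^j))
  for (i in 0:cfg$max_terms) {
    term <- .nb_coef(theta, i) * (1 - theta)^i * G2^i * inner
    s <- s + term
    if (all(abs(term) < cfg$tol) && i > 2) break
  }
  1 - s
}

#' @rdname pneitl_series
#' @export
dneitl_series <- function(x, theta, delta, cfg = series_config()) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  .check_x(x)
  G <- pitl(x, delta)
  g <- ditl(x, delta)
  s <- 0
  j <- seq_len(cfg$max_terms + 1L) - 1L
  inner <- drop(outer(G^2, j, `^`) %*% (choose(theta - 1, j) * (-1)^j))
  for (i in 0:cfg$max_terms) {
    term <- .nb_coef(theta + 1, i) * (1 - theta)^i * G^(2 * i) * inner
    s <- s + term
    if (all(abs(term) < cfg$tol) && i > 2) break
  }
  2 * theta^2 * g * G * s
}

#' Series form of the r-th raw NEITL moment
#'
#' Beta-function series for `E[X^r]`, used as a cross-check of the
#' quadrature moment in [neitl_moment()].  Requires `delta > r` (so the
#' leading beta term exists).  The rearranged series is numerically usable
#' in double precision only where its binomial sums terminate -- in
#' practice at `theta = 1`, where the family collapses and all expansion
#' indices except the final beta sum truncate exactly; elsewhere the
#' alternating inner binomial sum loses all precision.
#'
#' @param r positive integer moment order.
#' @param theta,delta positive shape parameters.
#' @param cfg a [series_config()].
#' @return the series value of the r-th raw moment.
#' @export
neitl_moment_series <- function(r, theta, delta, cfg = series_config()) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  if (delta <= r) {
    stop("series form requires delta > r for its leading beta term",
         call. = FALSE)
  }
  total <- 0
  for (i in 0:cfg$max_terms) {
    ci <- .nb_coef(theta + 1, i) * (1 - theta)^i
    sum_i <- 0
    for (j in 0:cfg$max_terms) {
      cj <- choose(theta - 1, j) * (-1)^j
      if (cj == 0 && j > theta) break
      u <- 2 * (i + j)
      l <- 0:(u + 1)
      cl <- choose(u + 1, l) * (-1)^l
      sum_l <- 0
      for (k in seq_along(l)) {
        cc <- delta * (l[k] + 1)  # ITL power in this mixture component
        q <- 0:cfg$max_terms
        bq <- choose(cc - 1, q) * beta(r + q + 2, cc - r)
        sum_l <- sum_l + cl[k] * sum(bq)
      }
      term <- cj * sum_l
      sum_i <- sum_i + term
      if (abs(term * ci) < cfg$tol && j > 2) break
    }
    contrib <- ci * sum_i
    total <- total + contrib
    if (abs(contrib) < cfg$tol && i > 2) break
  }
  2 * delta * 2 * theta^2 * total
}

#' Series form of the Renyi entropy
#'
#' Quadruple beta-function series for the order-`b` Renyi entropy, used as a
#' cross-check of the quadrature evaluation in [renyi_entropy()].  Requires
#' `b*(delta+1) > 1` for its beta terms to exist; like the moment series it
#' is numerically usable only where the binomial sums terminate, in
#' practice at `theta = 1`.
#'
#' @param theta,delta positive shape parameters.
#' @param b entropy order, positive and not 1.
#' @param cfg a [series_config()].
#' @return the series value of the Renyi entropy.
#' @export
renyi_entropy_series <- function(theta, delta, b, cfg = series_config()) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  .check_pos_scalar(b, "b")
  if (b == 1) stop("'b' must differ from 1", call. = FALSE)
  integral <- .renyi_integral_series(theta, delta, b, cfg)
  (1 / (1 - b)) * log(integral)
}

# series evaluation of  int f^b dx
.renyi_integral_series <- function(theta, delta, b, cfg) {
  total <- 0
  const <- (4 * theta^2 * delta)^b
  for (i in 0:cfg$max_terms) {
    ci <- .nb_coef(b * (theta + 1), i) * (1 - theta)^i
    sum_i <- 0
    for (j in 0:cfg$max_terms) {
      cj <- choose(b * (theta - 1), j) * (-1)^j
      u <- 2 * (i + j)
      sum_j <- 0
      for (k in 0:cfg$max_terms) {
        ck <- choose(b + u, k) * (-1)^k
        if (ck == 0 && k > b + u) break
        m <- 0:cfg$max_terms
        cc <- delta * k + b * (delta - 1)
        bm <- choose(cc, m) * beta(b + m + 1, delta * k + b * (delta + 1) - 1)
        term_k <- ck * sum(bm)
        sum_j <- sum_j + term_k
        if (abs(term_k) < cfg$tol && k > 2) break
      }
      term_j <- cj * sum_j
      sum_i <- sum_i + term_j
      if (abs(term_j * ci) < cfg$tol && j > 2) break
    }
    contrib <- ci * sum_i
    total <- total + contrib
    if (abs(contrib) < cfg$tol && i > 2) break
  }
  const * total
}

#' Series form of the common-theta stress-strength reliability
#'
#' Evaluates R = P(X2 < X1) for X1 ~ NEITL(theta, delta1) and
#' X2 ~ NEITL(theta, delta2) (a shared family shape) through the mixture
#' representations of F2 and f1, as a cross-check of the quadrature route
#' in [ss_reliability()].
#'
#' The expansion is
#' \deqn{R = 1 - 2\theta^2 \sum_{s_1, s_2} w_1(s_1) w_2(s_2)
#'   \sum_{l_1=0}^{2s_1+1} \sum_{l_2=0}^{2s_2} \binom{2s_1+1}{l_1}
#'   \binom{2s_2}{l_2} \frac{(-1)^{l_1+l_2}\,\delta_1}
#'   {\delta_1(l_1+1)+\delta_2 l_2},}
#' where `w1`, `w2` collect the binomial coefficients of the density and
#' CDF mixtures.  The inner alternating double binomial sum is evaluated
#' through its exact beta-integral representation
#' `int_0^1 (1-t)^{2 s1 + 1} (1 - t^(delta2/delta1))^{2 s2} dt`
#' (the naive sum loses all precision beyond `2 s ~ 50` in double
#' precision); the outer sums converge for `theta` in (0, 2), at a
#' practical rate only for `theta` near 1.
#'
#' @param theta common positive family shape, in (0, 2).
#' @param delta1,delta2 positive baseline shapes of strength and stress.
#' @param cfg a [series_config()].
#' @return the series value of R.
#' @export
ss_reliability_series <- function(theta, delta1, delta2,
                                  cfg = series_config()) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta1, "delta1")
  .check_pos_scalar(delta2, "delta2")
  if (theta >= 2) {
    stop("the common-theta series converges only for theta in (0, 2)",
         call. = FALSE)
  }
  S <- cfg$max_terms
  i <- 0:S
  # strength side: f1 mixture coefficients, (1-z)^-(theta+1) and (1-w)^(theta-1)
  a1 <- .nb_coef(theta + 1, i) * (1 - theta)^i
  b1 <- choose(theta - 1, i) * (-1)^i
  # stress side: F2 mixture coefficients, (1-z)^-theta and (1-w)^theta
  a2 <- .nb_coef(theta, i) * (1 - theta)^i
  b2 <- choose(theta, i) * (-1)^i
  conv <- function(a, b) {
    vapply(0:S, function(s) sum(a[1:(s + 1)] * b[(s + 1):1]), numeric(1))
  }
  w1 <- conv(a1, b1)
  w2 <- conv(a2, b2)
  # inner(s1, s2) = int_0^1 (1-t)^(2 s1 + 1) (1 - t^c)^(2 s2) dt, vectorized
  # over all (s1, s2) on Gauss-Legendre nodes
  gl <- .gauss_legendre_01(256L)
  cc <- delta2 / delta1
  M1 <- outer(gl$nodes, 2 * (0:S) + 1, function(t, p) (1 - t)^p)
  M2 <- outer(gl$nodes^cc, 2 * (0:S), function(tc, p) (1 - tc)^p)
  inner <- crossprod(M1 * gl$weights, M2)   # (S+1) x (S+1)
  1 - 2 * theta^2 * drop(t(w1) %*% inner %*% w2)
}

# Gauss-Legendre nodes/weights on (0, 1) by the Golub-Welsch eigenvalue
# method, cached per order
.gl_cache <- new.env(parent = emptyenv())
.gauss_legendre_01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  nodes <- (e$values + 1) / 2
  weights <- 2 * e$vectors[1, ]^2 / 2
  ord <- order(nodes)
  out <- list(nodes = nodes[ord], weights = weights[ord])
  .gl_cache[[key]] <- out
  out
}
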