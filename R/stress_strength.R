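# Stress-strength reliability R = P(X2 < X1) for independent NEITL strength
# X1 and stress X2.

#' Stress-strength reliability of two NEITL variables
#'
#' Computes `R = P(X2 < X1) = int F2(x) f1(x) dx` by adaptive quadrature for
#' independent `X1 ~ NEITL(theta1, delta1)` (strength) and
#' `X2 ~ NEITL(theta2, delta2)` (stress).  The parameters may differ in both
#' shapes; the common-theta series of [ss_reliability_series()] is the
#' cross-check where it applies.
#'
#' @param theta1,delta1 strength parameters.
#' @param theta2,delta2 stress parameters.
#' @return the reliability, a probability.
#' @examples
#' ss_reliability(2, 3, 2, 3)  # identical laws: 0.5
#' @export
ss_reliability <- function(theta1, delta1, theta2, delta2) {
  .check_pos_scalar(theta1, "theta1")
  .check_pos_scalar(delta1, "delta1")
  .check_pos_scalar(theta2, "theta2")
  .check_pos_scalar(delta2, "delta2")
  out <- tryCatch(
    stats::integrate(function(x) {
      pneitl(x, theta2, delta2) * dneitl(x, theta1, delta1)
    }, 0, Inf, rel.tol = 1e-10),
    error = function(e) stop("stress-strength quadrature did not converge: ",
                             conditionMessage(e), call. = FALSE))
  out$value
}

#' Fit a stress-strength model from two samples
#'
#' Fits the NEITL distribution separately to the strength sample `x1` and
#' the stress sample `x2` by the requested method (four free parameters, no
#' shared-shape constraint), then plugs the estimates into
#' [ss_reliability()].  For ML/MPS the interval for R comes from the delta
#' method with the block-diagonal covariance of the two independent fits;
#' for Bayes, the two posterior chains are propagated through the
#' reliability integral and an equal-tailed credible interval is returned
#' (the posterior mean of R is the point estimate).
#'
#' @param x1 strength sample.
#' @param x2 stress sample.
#' @param method `"mle"`, `"mps"` or `"bayes"`.
#' @param level confidence level for the interval on R.
#' @param R_draws for Bayes, number of (thinned) posterior draws propagated
#'   through the reliability integral.
#' @param starts1,starts2 optional per-sample starting values forwarded to
#'   [neitl_fit()].
#' @param ... passed to [neitl_fit()] (e.g. `search`, `prior`, `mcmc`,
#'   `seed`).
#' @return an object of class `neitl_ss`: a list with the two fits
#'   (`fit1`, `fit2`), the point estimate `R`, its `se` (posterior sd for
#'   Bayes) and interval `ci`.
#' @examples
#' x1 <- rneitl(40, 0.6, 2.5, seed = 1)
#' x2 <- rneitl(40, 0.6, 0.75, seed = 2)
#' ss_fit(x1, x2)
#' @export
ss_fit <- function(x1, x2, method = c("mle", "mps", "bayes"), level = 0.95,
                   R_draws = 1000L, starts1 = NULL, starts2 = NULL, ...) {
  method <- match.arg(method)
  f1 <- neitl_fit(x1, method = method, starts = starts1,
                  label = "strength", ...)
  f2 <- neitl_fit(x2, method = method, starts = starts2,
                  label = "stress", ...)
  if (method == "bayes") {
    n_use <- min(R_draws, length(f1$draws$theta), length(f2$draws$theta))
    idx1 <- round(seq(1, length(f1$draws$theta), length.out = n_use))
    idx2 <- round(seq(1, length(f2$draws$theta), length.out = n_use))
    Rd <- vapply(seq_len(n_use), function(i) {
      ss_reliability(f1$draws$theta[idx1[i]], f1$draws$delta[idx1[i]],
                     f2$draws$theta[idx2[i]], f2$draws$delta[idx2[i]])
    }, numeric(1))
    a <- (1 - level) / 2
    ci <- stats::quantile(Rd, c(a, 1 - a), names = FALSE)
    R <- mean(Rd); seR <- stats::sd(Rd)
    kind <- "credible"
  } else {
    p <- c(f1$estimate, f2$estimate)
    R <- ss_reliability(p[1], p[2], p[3], p[4])
    g <- .num_grad(function(q) ss_reliability(q[1], q[2], q[3], q[4]), p)
    V <- matrix(0, 4, 4)
    ok <- !is.null(f1$vcov) && !is.null(f2$vcov)
    if (ok) {
      V[1:2, 1:2] <- f1$vcov
      V[3:4, 3:4] <- f2$vcov
      seR <- sqrt(drop(t(g) %*% V %*% g))
    } else {
      seR <- NA_real_
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- c(R - z * seR, R + z * seR)
    kind <- "asymptotic"
  }
  structure(list(fit1 = f1, fit2 = f2, R = unname(R), se = unname(seR),
                 ci = ci, level = level, kind = kind, method = method),
            class = "neitl_ss")
}

#' @export
print.neitl_ss <- function(x, digits = 4, ...) {
  cat("Stress-strength reliability R = P(X2 < X1), method ",
      toupper(x$method), "\n", sep = "")
  cat("strength (theta1, delta1):",
      paste(round(x$fit1$estimate, digits), collapse = ", "), "\n")
  cat("stress   (theta2, delta2):",
      paste(round(x$fit2$estimate, digits), collapse = ", "), "\n")
  cat("R =", round(x$R, digits), " se =", round(x$se, digits),
      sprintf(" %d%% %s CI: [%s, %s]\n", round(100 * x$level), x$kind,
              round(x$ci[1], digits), round(x$ci[2], digits)))
  invisible(x)
}
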