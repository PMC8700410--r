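# Goodness-of-fit statistics on the probability-integral transform, and a
# multi-model ML comparison report.

#' One-sample goodness-of-fit statistics
#'
#' Kolmogorov-Smirnov (two-sided sup distance), Cramer-von Mises and
#' Anderson-Darling statistics of a sample against a fully specified
#' continuous CDF, evaluated on the sorted probability-integral transforms
#' `u_i = F(x_(i))`:
#' \deqn{KS = \max_i \max(i/n - u_i,\; u_i - (i-1)/n),}
#' \deqn{W^2 = 1/(12n) + \sum_i (u_i - (2i-1)/(2n))^2,}
#' \deqn{A^2 = -n - n^{-1} \sum_i (2i-1)(\log u_i + \log(1-u_{n+1-i})).}
#'
#' @param x sample values.
#' @param cdf a vectorized CDF function.
#' @return a single numeric value.
#' @examples
#' u <- c(0.25, 0.5, 0.75)
#' ks_stat(u, identity)  # 1/4 at the uniform grid i/(n+1)
#' @export
ks_stat <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(sort(x)))
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' @rdname ks_stat
#' @export
cvm_stat <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(sort(x)))
  i <- seq_len(n)
  1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
}

#' @rdname ks_stat
#' @export
ad_stat <- function(x, cdf) {
  n <- length(x)
  u <- sort(cdf(sort(x)))
  if (any(u <= 0 | u >= 1)) {
    bad <- which(u <= 0 | u >= 1)[1]
    stop("Anderson-Darling undefined: transformed value at sorted index ",
         bad, " is ", format(u[bad]), call. = FALSE)
  }
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log1p(-rev(u))))
}

#' Goodness-of-fit summary of a NEITL fit
#'
#' @param fit a [neitl_fit()] object.
#' @return named vector with `KS`, `CVM`, `AD`, `AIC`, `BIC`.
#' @export
gof_stats <- function(fit) {
  stopifnot(inherits(fit, "neitl_fit"))
  cdf <- function(q) pneitl(q, fit$estimate[1], fit$estimate[2])
  c(KS = ks_stat(fit$x, cdf), CVM = cvm_stat(fit$x, cdf),
    AD = ad_stat(fit$x, cdf), AIC = stats::AIC(fit), BIC = stats::BIC(fit))
}

# --- candidate models for the comparison report ---------------------------
# Each entry: number of parameters, log-density builder, cdf builder,
# starting grid on the log-parameter scale.

.dexpexp <- function(x, alpha, beta, log = FALSE) {
  # exponentiated exponential: F = (1 - exp(-beta x))^alpha
  ld <- log(alpha) + log(beta) - beta * x +
    (alpha - 1) * log(-expm1(-beta * x))
  if (log) ld else exp(ld)
}

.pexpexp <- function(q, alpha, beta) (-expm1(-beta * q))^alpha

.gof_models <- function() {
  lg <- seq(-3, 4, by = 1.75)
  list(
    neitl = list(
      k = 2L,
      nll = function(p, x) -sum(dneitl(x, p[1], p[2], log = TRUE)),
      cdf = function(p) function(q) pneitl(q, p[1], p[2]),
      starts = as.matrix(expand.grid(lg, lg)),
      par_names = c("theta", "delta")),
    itl = list(
      k = 1L,
      nll = function(p, x) -sum(ditl(x, p[1], log = TRUE)),
      cdf = function(p) function(q) pitl(q, p[1]),
      starts = matrix(lg, ncol = 1),
      par_names = "delta"),
    weibull = list(
      k = 2L,
      nll = function(p, x) -sum(stats::dweibull(x, p[1], p[2], log = TRUE)),
      cdf = function(p) function(q) stats::pweibull(q, p[1], p[2]),
      starts = as.matrix(expand.grid(lg, lg)),
      par_names = c("shape", "scale")),
    expexp = list(
      k = 2L,
      nll = function(p, x) -sum(.dexpexp(x, p[1], p[2], log = TRUE)),
      cdf = function(p) function(q) .pexpexp(q, p[1], p[2]),
      starts = as.matrix(expand.grid(lg, lg)),
      par_names = c("alpha", "beta")))
}

# generic multi-start ML for a candidate model on the log-parameter scale
.fit_candidate <- function(x, model) {
  obj <- function(lp, x) {
    v <- tryCatch(model$nll(exp(lp), x), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  for (i in seq_len(nrow(model$starts))) {
    o <- tryCatch(
      if (ncol(model$starts) == 1L) {
        stats::optim(model$starts[i, ], obj, x = x, method = "Brent",
                     lower = -10, upper = 10)
      } else {
        stats::optim(model$starts[i, ], obj, x = x, method = "Nelder-Mead",
                     control = list(maxit = 1000, reltol = 1e-10))
      },
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$value) &&
        (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) return(NULL)
  if (ncol(model$starts) > 1L) {
    polish <- tryCatch(
      stats::optim(best$par, obj, x = x, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  est <- exp(best$par)
  names(est) <- model$par_names
  H <- tryCatch(stats::optimHess(est, function(p) model$nll(p, x)),
                error = function(e) NULL)
  se <- if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc) && all(diag(vc) > 0)) sqrt(diag(vc)) else
      rep(NA_real_, length(est))
  } else rep(NA_real_, length(est))
  list(estimate = est, se = se, loglik = -best$value)
}

#' Multi-model goodness-of-fit comparison
#'
#' Fits each candidate model to the sample by multi-start maximum
#' likelihood and reports KS, Cramer-von Mises, Anderson-Darling, AIC and
#' BIC per model, flagging the minimizer of each criterion.  Supported
#' candidates: `"neitl"`, `"itl"`, `"weibull"`, `"expexp"` (exponentiated
#' exponential).  A model whose fit fails is recorded with `NA` statistics
#' rather than aborting the report.
#'
#' @param x positive sample values.
#' @param models character vector of candidate model names.
#' @return an object of class `gof_report`: a data frame with one row per
#'   model and attributes `fits` (the per-model estimates) and `best` (the
#'   per-criterion winners).
#' @examples
#' x <- rneitl(80, 2, 2, seed = 7)
#' compare_models(x)
#' @export
compare_models <- function(x, models = c("neitl", "itl", "weibull",
                                         "expexp")) {
  .check_sample(x)
  all_models <- .gof_models()
  models <- match.arg(models, names(all_models), several.ok = TRUE)
  n <- length(x)
  rows <- list(); fits <- list()
  for (nm in models) {
    mod <- all_models[[nm]]
    f <- .fit_candidate(x, mod)
    if (is.null(f)) {
      rows[[nm]] <- data.frame(model = nm, loglik = NA_real_, KS = NA_real_,
                               CVM = NA_real_, AD = NA_real_, AIC = NA_real_,
                               BIC = NA_real_)
      next
    }
    cdf <- mod$cdf(f$estimate)
    rows[[nm]] <- data.frame(
      model = nm, loglik = f$loglik,
      KS = ks_stat(x, cdf), CVM = cvm_stat(x, cdf),
      AD = tryCatch(ad_stat(x, cdf), error = function(e) NA_real_),
      AIC = 2 * mod$k - 2 * f$loglik,
      BIC = mod$k * log(n) - 2 * f$loglik)
    fits[[nm]] <- f
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  crit <- c("KS", "CVM", "AD", "AIC", "BIC")
  best <- vapply(crit, function(cc) {
    out$model[which.min(out[[cc]])]
  }, character(1))
  structure(out, fits = fits, best = best, class = c("gof_report",
                                                     "data.frame"))
}

#' @export
print.gof_report <- function(x, digits = 4, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df)
  best <- attr(x, "best")
  cat("criterion minima:",
      paste(names(best), best, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
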