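# Monte Carlo study harness: bias / MSE / interval-length summaries for the
# NEITL estimators and for the stress-strength reliability across methods
# and sample sizes.
#
# Common random numbers across sample sizes: each replicate draws one master
# sample of size max(n) and every n uses its first n observations (an i.i.d.
# prefix is itself a valid sample).  This couples the estimators across n,
# which sharpens comparisons of MSE between sample sizes at a fixed number
# of replications.

# fit one replicate sample by one method; returns estimates, interval
# lengths for the parameters, and interval lengths for SF/HF at each Q
.sim_fit_one <- function(x, method, times, level, prior, mcmc,
                         start = NULL) {
  fit <- neitl_fit(x, method = method, search = "local", starts = start,
                   prior = prior, mcmc = mcmc)
  ci <- confint(fit, level = level)
  rel <- reliability_at(fit, times, level = level)
  list(est = fit$estimate,
       len = ci[, "upper"] - ci[, "lower"],
       R = rel$R, H = rel$H,
       lenR = rel$R_upper - rel$R_lower,
       lenH = rel$H_upper - rel$H_lower)
}

.summarize_cell <- function(true_vals, est_mat, len_mat) {
  # est_mat: replicates x quantities; len_mat same shape
  err <- sweep(est_mat, 2, true_vals)
  mse <- colMeans(err^2)
  data.frame(quantity = colnames(est_mat),
             true = unname(true_vals),
             AE = unname(colMeans(err)),          # average bias
             mean_est = unname(colMeans(est_mat)),
             MSE = unname(mse),
             MSE_mcse = unname(apply(err^2, 2, stats::sd) /
                                 sqrt(nrow(est_mat))),
             L.CI = unname(colMeans(len_mat, na.rm = TRUE)),
             row.names = NULL)
}

#' Monte Carlo study of the NEITL estimators
#'
#' For each replicate, draws a NEITL sample, fits it by each requested
#' method, and records the parameter estimates, the plug-in survival and
#' hazard values `R_k = S(t_k)`, `H_k = h(t_k)`, and all interval lengths.
#' The evaluation times are the true quantiles `t_k = Q(q_k; theta, delta)`
#' at the levels `Q`, so that the true survival value in every cell is
#' `1 - q_k` whatever the parameters (the average reported survival
#' estimate at level 0.25 is ~0.75 in every parameter configuration).
#' Summaries per (n, method, quantity): average bias (`AE`), mean estimate,
#' mean squared error (`MSE`, with its Monte Carlo standard error), and
#' mean interval length (`L.CI`).
#'
#' ML and MPS replicate fits use `search = "local"` in [neitl_fit()],
#' started at the true parameter values (the usual Monte Carlo convention):
#' the study measures the consistent root of the estimating equations, not
#' the global optimum, which under the model's weak identifiability is
#' heavy-tailed (see the package vignette).  Sample sizes share common
#' random numbers (nested prefixes of one master sample per replicate).
#' Replicates whose fit fails (including local searches that diverge along
#' the likelihood ridge) are dropped and counted; a cell with more than 5%
#' failures is flagged.
#'
#' @param theta,delta true parameter values.
#' @param n vector of sample sizes.
#' @param methods subset of `"mle"`, `"mps"`, `"bayes"`.
#' @param n_rep number of Monte Carlo replications per cell.
#' @param Q quantile levels setting the survival/hazard evaluation times.
#' @param level confidence level for interval lengths.
#' @param seed integer seed making the whole study reproducible.
#' @param prior,mcmc Bayesian settings; the default chain (2000 iterations,
#'   500 burn-in) is deliberately short to keep study cells tractable.
#' @return an object of class `neitl_sim`: a data frame with columns
#'   `n`, `method`, `quantity`, `true`, `AE`, `mean_est`, `MSE`,
#'   `MSE_mcse`, `L.CI`, plus attribute `failures` (a per-cell count).
#' @examples
#' mc_study(0.5, 0.5, n = c(30, 60), methods = "mle", n_rep = 20, seed = 1)
#' @export
mc_study <- function(theta, delta, n = c(30, 80, 150),
                     methods = c("mle", "mps", "bayes"), n_rep = 500,
                     Q = c(0.25, 0.35), level = 0.95, seed = NULL,
                     prior = neitl_prior(),
                     mcmc = mcmc_control(2000L, 500L)) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  methods <- match.arg(methods, several.ok = TRUE)
  n <- sort(unique(as.integer(n)))
  qn <- c("theta", "delta", paste0("R", seq_along(Q)),
          paste0("H", seq_along(Q)))
  times <- qneitl(Q, theta, delta)
  true_vals <- c(theta, delta, 1 - Q, hneitl(times, theta, delta))
  names(true_vals) <- qn
  run <- function() {
    res <- list(); fail <- list()
    est <- array(NA_real_, c(n_rep, length(qn), length(n), length(methods)))
    len <- est
    for (r in seq_len(n_rep)) {
      master <- qneitl(stats::runif(max(n)), theta, delta)
      for (ni in seq_along(n)) {
        xr <- master[seq_len(n[ni])]
        for (mi in seq_along(methods)) {
          one <- tryCatch(
            .sim_fit_one(xr, methods[mi], times, level, prior, mcmc,
                         start = matrix(log(c(theta, delta)), 1)),
            error = function(e) NULL)
          if (is.null(one)) next
          est[r, , ni, mi] <- c(one$est, one$R, one$H)
          len[r, , ni, mi] <- c(one$len, one$lenR, one$lenH)
        }
      }
    }
    for (ni in seq_along(n)) {
      for (mi in seq_along(methods)) {
        e <- est[, , ni, mi, drop = FALSE]
        dim(e) <- c(n_rep, length(qn)); colnames(e) <- qn
        l <- len[, , ni, mi, drop = FALSE]
        dim(l) <- c(n_rep, length(qn))
        ok <- stats::complete.cases(e)
        cell <- .summarize_cell(true_vals, e[ok, , drop = FALSE],
                                l[ok, , drop = FALSE])
        cell <- cbind(n = n[ni], method = methods[mi], cell)
        key <- paste(n[ni], methods[mi])
        res[[key]] <- cell
        fail[[key]] <- sum(!ok)
      }
    }
    list(res = res, fail = fail)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  df <- do.call(rbind, out$res)
  rownames(df) <- NULL
  failures <- unlist(out$fail)
  flagged <- failures > 0.05 * n_rep
  if (any(flagged)) {
    warning("more than 5% replicate failures in cell(s): ",
            paste(names(failures)[flagged], collapse = ", "))
  }
  structure(df, failures = failures, n_rep = n_rep,
            class = c("neitl_sim", "data.frame"))
}

#' Monte Carlo study of the stress-strength estimator
#'
#' Per replicate, draws independent strength and stress samples, fits both
#' margins by each method via [ss_fit()], and summarizes the four parameter
#' estimates and the reliability `R = P(X2 < X1)` exactly as in
#' [mc_study()].  Sample-size pairs share common random numbers.
#'
#' @param theta1,delta1,theta2,delta2 true parameters (strength, stress).
#' @param nm a matrix (or list of length-2 vectors) of sample-size pairs
#'   `(n, m)`.
#' @param methods,n_rep,level,seed,prior,mcmc as in [mc_study()].
#' @return an object of class `neitl_sim` with `n` replaced by the label
#'   `"n,m"`.
#' @examples
#' mc_ss_study(0.6, 0.75, 0.65, 2.5, nm = rbind(c(25, 30)),
#'             methods = "mle", n_rep = 10, seed = 1)
#' @export
mc_ss_study <- function(theta1, delta1, theta2, delta2,
                        nm = rbind(c(25, 30), c(80, 70), c(150, 120)),
                        methods = c("mle", "mps", "bayes"), n_rep = 500,
                        level = 0.95, seed = NULL,
                        prior = neitl_prior(),
                        mcmc = mcmc_control(2000L, 500L)) {
  if (is.list(nm)) nm <- do.call(rbind, nm)
  methods <- match.arg(methods, several.ok = TRUE)
  qn <- c("theta1", "delta1", "theta2", "delta2", "R")
  true_R <- ss_reliability(theta1, delta1, theta2, delta2)
  true_vals <- c(theta1, delta1, theta2, delta2, true_R)
  names(true_vals) <- qn
  z <- stats::qnorm(1 - (1 - level) / 2)
  run <- function() {
    res <- list(); fail <- list()
    est <- array(NA_real_, c(n_rep, length(qn), nrow(nm), length(methods)))
    len <- est
    for (r in seq_len(n_rep)) {
      m1 <- qneitl(stats::runif(max(nm[, 1])), theta1, delta1)
      m2 <- qneitl(stats::runif(max(nm[, 2])), theta2, delta2)
      for (si in seq_len(nrow(nm))) {
        x1 <- m1[seq_len(nm[si, 1])]
        x2 <- m2[seq_len(nm[si, 2])]
        for (mi in seq_along(methods)) {
          one <- tryCatch({
            s <- ss_fit(x1, x2, method = methods[mi], level = level,
                        search = "local",
                        starts1 = matrix(log(c(theta1, delta1)), 1),
                        starts2 = matrix(log(c(theta2, delta2)), 1),
                        prior = prior, mcmc = mcmc)
            ci1 <- confint(s$fit1, level = level)
            ci2 <- confint(s$fit2, level = level)
            list(est = c(s$fit1$estimate, s$fit2$estimate, s$R),
                 len = c(ci1[, 2] - ci1[, 1], ci2[, 2] - ci2[, 1],
                         s$ci[2] - s$ci[1]))
          }, error = function(e) NULL)
          if (is.null(one)) next
          est[r, , si, mi] <- one$est
          len[r, , si, mi] <- one$len
        }
      }
    }
    for (si in seq_len(nrow(nm))) {
      for (mi in seq_along(methods)) {
        e <- est[, , si, mi, drop = FALSE]
        dim(e) <- c(n_rep, length(qn)); colnames(e) <- qn
        l <- len[, , si, mi, drop = FALSE]
        dim(l) <- c(n_rep, length(qn))
        ok <- stats::complete.cases(e)
        cell <- .summarize_cell(true_vals, e[ok, , drop = FALSE],
                                l[ok, , drop = FALSE])
        cell <- cbind(n = paste(nm[si, ], collapse = ","),
                      method = methods[mi], cell)
        key <- paste(paste(nm[si, ], collapse = ","), methods[mi])
        res[[key]] <- cell
        fail[[key]] <- sum(!ok)
      }
    }
    list(res = res, fail = fail)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  df <- do.call(rbind, out$res)
  rownames(df) <- NULL
  failures <- unlist(out$fail)
  flagged <- failures > 0.05 * n_rep
  if (any(flagged)) {
    warning("more than 5% replicate failures in cell(s): ",
            paste(names(failures)[flagged], collapse = ", "))
  }
  structure(df, failures = failures, n_rep = n_rep,
            class = c("neitl_sim", "data.frame"))
}

#' Wide AE / MSE / L.CI table of a simulation study
#'
#' Reshapes a [mc_study()] / [mc_ss_study()] result into the conventional
#' report layout: one row per (n, quantity), and `AE`, `MSE`, `L.CI`
#' columns per method.  An empty input yields a header-only (zero-row)
#' table.
#'
#' @param s a `neitl_sim` object (or compatible data frame).
#' @param digits rounding applied to the numeric columns.
#' @return a plain data frame.
#' @export
format_sim_table <- function(s, digits = 4) {
  df <- as.data.frame(s)
  methods <- unique(df$method)
  if (nrow(df) == 0 || length(methods) == 0) {
    return(data.frame(n = character(0), quantity = character(0)))
  }
  keys <- unique(df[c("n", "quantity")])
  out <- keys
  for (m in methods) {
    sub <- df[df$method == m, c("n", "quantity", "AE", "MSE", "L.CI")]
    names(sub)[3:5] <- paste(c("AE", "MSE", "L.CI"), m, sep = ".")
    out <- merge(out, sub, by = c("n", "quantity"), sort = FALSE)
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  out
}

#' @export
print.neitl_sim <- function(x, digits = 4, ...) {
  cat("Monte Carlo study,", attr(x, "n_rep"), "replications per cell\n")
  print(format_sim_table(x, digits = digits))
  f <- attr(x, "failures")
  if (any(f > 0)) cat("replicate failures:",
                      paste(names(f)[f > 0], f[f > 0], collapse = "; "),
                      "\n")
  invisible(x)
}
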