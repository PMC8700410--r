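# Bayesian estimation of (theta, delta) under independent gamma priors by
# Metropolis-within-Gibbs sampling.
#
# Each parameter is updated in turn with a random-walk proposal on the log
# scale (with the log-scale Jacobian in the acceptance ratio), against its
# full conditional: the joint log posterior minus terms free of that
# parameter.  Proposal standard deviations are adapted toward a ~40%
# acceptance rate during burn-in only, so the retained chain is a fixed
# Markov kernel.

#' Gamma prior specification
#'
#' Independent gamma priors `theta ~ Gamma(a1, b1)` and
#' `delta ~ Gamma(a2, b2)` (shape/rate).  The default
#' `a = b = 0.1` is weakly informative (prior mean 1, variance 10).
#'
#' @param a1,b1 shape and rate for `theta`.
#' @param a2,b2 shape and rate for `delta`.
#' @return a list with class `neitl_prior`.
#' @export
neitl_prior <- function(a1 = 0.1, b1 = 0.1, a2 = 0.1, b2 = 0.1) {
  for (nm in c("a1", "b1", "a2", "b2")) .check_pos_scalar(get(nm), nm)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2), class = "neitl_prior")
}

#' MCMC settings
#'
#' @param n_iter total chain length.
#' @param burn_in iterations discarded (and used for proposal adaptation).
#' @param proposal_sd initial random-walk standard deviations on
#'   `(log theta, log delta)`.
#' @return a list with class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 10000L, burn_in = 2000L,
                         proposal_sd = c(0.5, 0.5)) {
  if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'",
                              call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 proposal_sd = proposal_sd), class = "mcmc_control")
}

#' NEITL log-posterior
#'
#' Log-likelihood plus the gamma log-prior
#' `(a1-1) log theta - b1 theta + (a2-1) log delta - b2 delta`, up to an
#' additive constant.  With an empty sample (`x = numeric(0)`) the
#' likelihood term vanishes and the prior alone is returned, which makes
#' prior-only MCMC possible.
#'
#' @param theta,delta positive shape parameters.
#' @param x positive sample values (possibly empty).
#' @param prior a [neitl_prior()].
#' @return a single number.
#' @export
neitl_log_posterior <- function(theta, delta, x, prior = neitl_prior()) {
  .check_pos_scalar(theta, "theta")
  .check_pos_scalar(delta, "delta")
  lp <- (prior$a1 - 1) * log(theta) - prior$b1 * theta +
    (prior$a2 - 1) * log(delta) - prior$b2 * delta
  if (length(x)) lp <- lp + neitl_loglik(theta, delta, x)
  lp
}

.neitl_bayes_fit <- function(x, prior, mcmc, seed, label,
                             allow_empty = FALSE) {
  if (!allow_empty) .check_sample(x)
  run <- function() .mwg_sampler(x, prior, mcmc)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  keep <- (mcmc$burn_in + 1L):mcmc$n_iter
  draws <- list(theta = res$theta[keep], delta = res$delta[keep])
  est <- c(theta = mean(draws$theta), delta = mean(draws$delta))
  se <- c(theta = stats::sd(draws$theta), delta = stats::sd(draws$delta))
  if (any(res$acc_rate < 0.05) || any(res$acc_rate > 0.95)) {
    warning("MCMC acceptance rate outside (0.05, 0.95): ",
            paste(round(res$acc_rate, 3), collapse = ", "))
  }
  ll <- if (length(x)) neitl_loglik(est[1], est[2], x) else NA_real_
  structure(list(
    estimate = est, se = se,
    vcov = stats::cov(cbind(draws$theta, draws$delta)),
    objective = ll, loglik = ll,
    draws = draws, acc_rate = res$acc_rate,
    prior = prior, mcmc = mcmc, seed = seed,
    converged = TRUE, method = "bayes", n = length(x), x = x,
    label = label),
    class = c("neitl_bayes", "neitl_fit"))
}

# Metropolis-within-Gibbs on (log theta, log delta).  The log target for
# log-parameters is log posterior + log theta + log delta (Jacobian).
.mwg_sampler <- function(x, prior, mcmc) {
  n_iter <- mcmc$n_iter
  lt <- 0; ld <- 0                       # start at theta = delta = 1
  sd_p <- mcmc$proposal_sd
  ltarget <- function(lt, ld) {
    tryCatch(
      neitl_log_posterior(exp(lt), exp(ld), x, prior) + lt + ld,
      error = function(e) -Inf)
  }
  cur <- ltarget(lt, ld)
  th_out <- de_out <- numeric(n_iter)
  acc <- c(0L, 0L); acc_win <- c(0L, 0L); win <- 0L
  for (it in seq_len(n_iter)) {
    # update log theta | log delta
    prop <- lt + stats::rnorm(1, 0, sd_p[1])
    cand <- ltarget(prop, ld)
    if (log(stats::runif(1)) < cand - cur) {
      lt <- prop; cur <- cand; acc[1] <- acc[1] + 1L
      acc_win[1] <- acc_win[1] + 1L
    }
    # update log delta | log theta
    prop <- ld + stats::rnorm(1, 0, sd_p[2])
    cand <- ltarget(lt, prop)
    if (log(stats::runif(1)) < cand - cur) {
      ld <- prop; cur <- cand; acc[2] <- acc[2] + 1L
      acc_win[2] <- acc_win[2] + 1L
    }
    th_out[it] <- exp(lt); de_out[it] <- exp(ld)
    win <- win + 1L
    # adapt proposal scales toward ~40% acceptance, burn-in only
    if (it <= mcmc$burn_in && win == 50L) {
      rate <- acc_win / 50
      sd_p <- sd_p * exp(0.5 * (rate - 0.4))
      acc_win <- c(0L, 0L); win <- 0L
    }
  }
  list(theta = th_out, delta = de_out, acc_rate = acc / n_iter,
       proposal_sd = sd_p)
}

#' Prior-only posterior draws
#'
#' Runs the same Metropolis-within-Gibbs sampler with an empty sample, so
#' the target is the prior itself.  Useful for validating the sampler: the
#' draws must reproduce the gamma prior moments.
#'
#' @param prior a [neitl_prior()].
#' @param mcmc an [mcmc_control()].
#' @param seed optional integer seed.
#' @return a `neitl_bayes` object (with `n = 0`).
#' @export
prior_draws <- function(prior = neitl_prior(), mcmc = mcmc_control(),
                        seed = NULL) {
  .neitl_bayes_fit(numeric(0), prior, mcmc, seed, label = "prior only",
                   allow_empty = TRUE)
}

#' @export
confint.neitl_bayes <- function(object, parm = c("theta", "delta"),
                                level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  a <- (1 - level) / 2
  out <- t(vapply(parm, function(p) {
    stats::quantile(object$draws[[p]], c(a, 1 - a), names = FALSE)
  }, numeric(2)))
  colnames(out) <- c("lower", "upper")
  attr(out, "kind") <- "credible"
  attr(out, "level") <- level
  out
}

#' @export
print.neitl_bayes <- function(x, digits = 4, ...) {
  cat("NEITL Bayesian fit (posterior mean under squared-error loss), n = ",
      x$n, "\n", sep = "")
  tab <- cbind(estimate = x$estimate, post_sd = x$se)
  print(round(tab, digits))
  cat("chain length:", x$mcmc$n_iter, " burn-in:", x$mcmc$burn_in,
      " acceptance:", paste(round(x$acc_rate, 2), collapse = "/"), "\n")
  invisible(x)
}
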