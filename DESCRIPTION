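Package: neitl
Title: The New Exponential Inverted Topp-Leone Lifetime Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Distribution functions, moments, entropies and reliability
    analysis for the two-parameter new exponential inverted Topp-Leone
    (NEITL) lifetime distribution and its one-parameter inverted
    Topp-Leone baseline.  Parameters are estimated by maximum likelihood,
    maximum product of spacings, or Bayesian Markov chain Monte Carlo
    with independent gamma priors, with asymptotic, bootstrap and
    credible intervals.  Includes plug-in estimation of survival and
    hazard functions at fixed times, stress-strength reliability
    P(X2 < X1) for two independent NEITL variables, goodness-of-fit
    model comparison (Kolmogorov-Smirnov, Cramer-von Mises,
    Anderson-Darling, AIC, BIC), and a Monte Carlo study harness for
    bias, mean squared error and interval-length summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
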