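# parameter sets exercised across the distribution tests
param_grid <- list(
  c(theta = 0.5, delta = 0.5),
  c(theta = 0.5, delta = 3),
  c(theta = 3, delta = 0.5),
  c(theta = 3, delta = 3),
  c(theta = 2, delta = 3),
  c(theta = 1.3, delta = 0.8)
)

# small deterministic NEITL sample used by several estimation tests
fixture_sample <- function(n = 60, theta = 2, delta = 1, seed = 101) {
  rneitl(n, theta, delta, seed = seed)
}
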