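# Shared fixtures: all built in code at test time.

base_params <- function(...) {
  overrides <- list(...)
  if (length(overrides)) load_parameters(overrides, strict = FALSE)
  else load_parameters()
}

# A random but valid parameter set drawn from the PSA distributions.
perturbed_params <- function(seed) {
  sample_parameter_set(load_parameters(), seed = seed)
}

# Parameters that make the two arms structurally identical: same uptake and
# the in-person cost model on both arms.
equalised_params <- function() {
  load_parameters(list(
    accept_internet = 0.633, comply_internet = 0.839,
    rel_effect_internet = 1.0,
    therapist_time_share_internet = 1.0, platform_overhead = 0
  ), strict = FALSE)
}

# Degenerate parameter set: every distribution forced to 'fixed', so any
# sampler draw reproduces the base values.
all_fixed_params <- function() {
  p <- load_parameters()
  reg <- attr(p, "registry")
  reg$dist <- "fixed"
  reg$low <- NA_real_
  reg$high <- NA_real_
  attr(p, "registry") <- reg
  p
}

expect_within_se <- function(estimate, reference, se, k = 3, label = NULL) {
  expect_lt(abs(estimate - reference), k * se, label = label)
}
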