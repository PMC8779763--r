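# Shared fixtures, built in code.

# Published-style base-model parameters (constant expansion).
base_params <- function() {
  pk_parameters(V1 = 2.43, V2 = 0.00516, K = 0.033, K12 = 0.183,
                K21 = 0.00287)
}

base_model <- function() structural_model(base_params())

hill_expansion <- function() {
  expansion_fn("hill_exp", Emax = 6.99, T50 = 49, Hill = 3.71)
}

sqrt_expansion <- function() {
  expansion_fn("sqrt_sigmoid", B1 = 1150, B2 = 80.2, B3 = 8.84)
}

logistic_expansion <- function() {
  expansion_fn("logistic", M1 = 99.1, M2 = 0.0701, M3 = 8.85)
}

all_sigmoids <- function() {
  list(hill_exp = hill_expansion(), logistic = logistic_expansion(),
       sqrt_sigmoid = sqrt_expansion())
}

# Generator truth for synthetic studies: a hill_exp world calibrated to the
# emulated experiment's qualitative behaviour (serum ~1 ug/mL scale, spleen
# trough concentrations rising monotonically to ~30x serum, half-life
# growing from days to hundreds of days).
truth_params <- function() {
  pk_parameters(V1 = 60, V2 = 0.1, K = 0.3, K12 = 0.3, K21 = 6)
}

truth_expansion <- function() expansion_fn("hill_exp", Emax = 5, T50 = 60,
                                           Hill = 3)

truth_model <- function(expansion = truth_expansion()) {
  structural_model(truth_params(), expansion)
}

study_schedule <- function() build_schedule(25, 20)

# One bolus at t = 0 (for analytic-oracle comparisons).
bolus_schedule <- function(amount = 25) {
  s <- data.frame(time = 0, amount = amount)
  class(s) <- c("dose_schedule", "data.frame")
  attr(s, "horizon") <- 150
  s
}

conc_stream <- function(sim, stream) {
  sim$concentration[sim$compartment == stream]
}
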