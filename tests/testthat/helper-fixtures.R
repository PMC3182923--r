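# shared fixtures and independent oracles

# a closed-form-friendly parameter set: linear expression-benefit
# (z_exponent = 1) with saturating cost
toy_params <- function() {
  lac_growth_params(
    g0 = 1,
    induction = lac_induction_params(z_basal = 0.01, z_max = 1, k_half = 6,
                                     hill_n = 2, k_anti = 1000),
    cost = lac_cost_params(eta0 = 0.04, m_sat = 1.25),
    benefit = lac_benefit_params(delta = 1, k_pgal = 200, hill_p = 2,
                                 z_exponent = 1))
}

# random valid parameter draws for property tests; z_exponent = 1 for half
# of the draws so the analytic branch is exercised
random_params <- function(i) {
  withr::with_seed(1000 + i, {
    zb <- runif(1, 0, 0.05)
    lac_growth_params(
      g0 = runif(1, 0.5, 1.5),
      induction = lac_induction_params(
        z_basal = zb, z_max = 1, k_half = runif(1, 2, 20),
        hill_n = runif(1, 1, 3), k_anti = runif(1, 500, 2000)),
      cost = lac_cost_params(eta0 = runif(1, 0.02, 0.3),
                             m_sat = runif(1, 1.1, 4)),
      benefit = lac_benefit_params(
        delta = runif(1, 0.5, 3), k_pgal = runif(1, 100, 600),
        hill_p = runif(1, 1, 3),
        z_exponent = if (i %% 2) 1 else runif(1, 0.2, 1)))
  })
}

# brute-force optimal expression: dense grid argmax of benefit minus cost
zopt_bruteforce <- function(P, params, n = 1e4) {
  zb <- params$induction$z_basal
  zm <- params$induction$z_max
  zg <- seq(zb, zm, length.out = n)
  obj <- expression_benefit(zg, P, params) -
    expression_cost(zg, params, z_basal = zb)
  zg[which.max(obj)]
}

# iterated per-generation map, the oracle for the logistic closed form
mutant_frequency_iterated <- function(s, x0, t) {
  x <- x0
  for (i in seq_len(t)) x <- x * (1 + s) / (1 + s * x)
  x
}

default_truth <- function() {
  read_ground_truth(system.file("extdata", "ground_truth.json",
                                package = "lacoptim", mustWork = TRUE))
}
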