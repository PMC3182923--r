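test_that("closed-form mutant frequency equals the iterated map", {
  for (s in c(-0.2, 0, 0.013, 0.055, 0.5)) {
    x_closed <- mutant_frequency(s, 1e-7, 1000)
    x_iter <- mutant_frequency_iterated(s, 1e-7, 1000)
    expect_lt(abs(x_closed - x_iter), 1e-12)
  }
  expect_equal(mutant_frequency(0, 0.3, c(0, 10, 1e4)), rep(0.3, 3),
               tolerance = 1e-12)
  # a s = 0.055 sweep from 1e-7 crosses one half at ~301 generations
  t_half <- uniroot(function(t) mutant_frequency(0.055, 1e-7, t) - 0.5,
                    c(1, 1000))$root
  expect_equal(t_half, log(1e7) / log(1.055), tolerance = 1e-6)
  expect_equal(round(t_half), 301)
  expect_error(mutant_frequency(-1, 0.5, 1), "exceed -1")
  expect_error(mutant_frequency(0.1, 0, 1), "strictly between")
})

test_that("deterministic serial transfer matches the logistic closed form", {
  d <- lac_default_params()
  wt <- lac_genotype("wt", d$induction)
  mut <- constitutive_genotype(d)
  proto <- lac_transfer_protocol(dilution_factor = 400)
  tr <- simulate_serial_transfer(list(wt, mut), c(1 - 1e-7, 1e-7),
                                 lac_schedule(0, 350), proto, d,
                                 n_generations = 300)
  g_wt <- growth_rate(0, 350, d)
  g_mut <- growth_rate(0, 350, lacoptim:::genotype_params(mut, d))
  s <- 2^((g_mut - g_wt) / g_wt) - 1
  expect_lt(max(abs(tr$freq_mutant -
                      mutant_frequency(s, 1e-7, tr$generation))), 1e-9)
  # single genotype: expression constant over time
  tr1 <- simulate_serial_transfer(list(wt), 1, lac_schedule(0, 350), proto,
                                  d, n_generations = 100)
  expect_equal(diff(range(tr1$expr_induced)), 0)
  expect_equal(diff(range(tr1$expr_uninduced)), 0)
})

test_that("splitting cycles into sub-cycles leaves the dynamics unchanged", {
  d <- lac_default_params()
  wt <- lac_genotype("wt", d$induction)
  mut <- constitutive_genotype(d)
  tr_big <- simulate_serial_transfer(
    list(wt, mut), c(1 - 1e-6, 1e-6), lac_schedule(0, 350),
    lac_transfer_protocol(dilution_factor = 400), d, n_generations = 86)
  tr_small <- simulate_serial_transfer(
    list(wt, mut), c(1 - 1e-6, 1e-6), lac_schedule(0, 350),
    lac_transfer_protocol(dilution_factor = 20), d, n_generations = 86)
  # dilution 400 = 20^2: every second fine-grained sample coincides
  sub <- tr_small[seq(1, nrow(tr_small), by = 2), ]
  n <- min(nrow(sub), nrow(tr_big))
  expect_lt(max(abs(sub$freq_mutant[1:n] - tr_big$freq_mutant[1:n])), 1e-9)
})

test_that("frequencies stay normalized in both bottleneck modes", {
  d <- lac_default_params()
  genos <- list(lac_genotype("wt", d$induction), constitutive_genotype(d),
                lac_genotype("half", lac_induction_params(
                  z_basal = 0.3, z_max = 1, k_half = 13, hill_n = 1.6,
                  k_anti = 1000)))
  for (mode in c("deterministic", "binomial")) {
    proto <- lac_transfer_protocol(bottleneck_mode = mode)
    tr <- simulate_serial_transfer(genos, c(0.8, 0.1, 0.1),
                                   lac_schedule(c(0, 220), c(350, 0)),
                                   proto, d, mutation_rate = 1e-6,
                                   n_generations = 200, seed = 3)
    freqs <- as.matrix(tr[, c("freq_wt", "freq_constitutive", "freq_half")])
    expect_true(all(freqs >= 0 & freqs <= 1))
    expect_true(all(abs(rowSums(freqs) - 1) < 1e-9))
  }
})

test_that("the deterministic winner has the highest schedule-averaged growth", {
  d <- lac_default_params()
  genos <- list(lac_genotype("wt", d$induction), constitutive_genotype(d),
                lac_genotype("half", lac_induction_params(
                  z_basal = 0.3, z_max = 1, k_half = 13, hill_n = 1.6,
                  k_anti = 1000)))
  sched <- lac_schedule(c(0, 220), c(350, 0))
  proto <- lac_transfer_protocol()
  # brute-force oracle: per-cycle log gain summed over the schedule period
  gains <- vapply(genos, function(gn) {
    p <- lacoptim:::genotype_params(gn, d)
    sum(vapply(seq_len(nrow(sched)), function(k) {
      g_ref <- growth_rate(sched$iptg[k], sched$pgal[k], d)
      growth_rate(sched$iptg[k], sched$pgal[k], p) / g_ref
    }, numeric(1)))
  }, numeric(1))
  winner <- which.max(gains)
  tr <- simulate_serial_transfer(genos, rep(1 / 3, 3), sched, proto, d,
                                 n_generations = 2000)
  freqs <- unlist(tr[nrow(tr), c("freq_wt", "freq_constitutive", "freq_half")])
  expect_equal(unname(which.max(freqs)), winner)
  expect_gt(max(freqs), 0.99)
})

test_that("binomial bottlenecks at 1e7 average to the deterministic limit", {
  d <- lac_default_params()
  wt <- lac_genotype("wt", d$induction)
  mut <- constitutive_genotype(d)
  sched <- lac_schedule(0, 350)
  proto_det <- lac_transfer_protocol(dilution_factor = 1000,
                                     culture_volume_ml = 10)
  proto_bin <- lac_transfer_protocol(dilution_factor = 1000,
                                     culture_volume_ml = 10,
                                     bottleneck_mode = "binomial")
  expect_equal(lacoptim:::bottleneck_size(proto_bin), 1e7)
  det <- simulate_serial_transfer(list(wt, mut), c(0.999, 0.001), sched,
                                  proto_det, d, n_generations = 100)
  finals <- vapply(1:30, function(sd) {
    tr <- simulate_serial_transfer(list(wt, mut), c(0.999, 0.001), sched,
                                   proto_bin, d, n_generations = 100,
                                   seed = sd)
    tr$freq_mutant[nrow(tr)]
  }, numeric(1))
  mc_err <- 3 * sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - det$freq_mutant[nrow(det)]), mc_err + 0.01)
})

test_that("evolution outcomes match the observed fixation pattern", {
  d <- lac_default_params()
  wt <- lac_genotype("wt", d$induction)
  mut <- constitutive_genotype(d)
  proto <- lac_transfer_protocol()
  run <- function(sched) {
    tr <- simulate_serial_transfer(list(wt, mut), c(1 - 1e-7, 1e-7), sched,
                                   proto, d, n_generations = 800)
    tr$freq_mutant[nrow(tr)]
  }
  # constitutive mutant sweeps under carbon without inducer
  expect_gt(run(lac_schedule(0, 350)), 0.99)
  # and under both alternating regimes that favored overall expression gains
  expect_gt(run(lac_schedule(c(2, 220), c(350, 39))), 0.99)
  expect_gt(run(lac_schedule(c(0, 2), c(0, 350))), 0.99)
  # wild type persists without selection pressure on expression
  expect_lt(run(lac_schedule(0, 0)), 0.01)
  expect_lt(run(lac_schedule(220, 350)), 0.01)
})

test_that("selection fitting round-trips noise-free and noisy sweeps", {
  zb <- lac_default_params()$induction$z_basal
  z_wt <- c(zb, 1)
  tr <- generate_trajectory(0.055, 1e-7, z_wt, c(1, 1), obs_noise_cv = 0,
                            seed = 1)
  fit <- fit_selection_coefficient(tr, z_wt, c(1, 1))
  expect_equal(fit$s, 0.055, tolerance = 0.01)
  expect_equal(fit$x0, 1e-7, tolerance = 0.05)
  expect_true(fit$converged)
  # downward sweep: mutant loses induced expression
  tr_dn <- generate_trajectory(0.067, 1e-7, z_wt, c(zb, 0.05),
                               obs_noise_cv = 0, seed = 1)
  fit_dn <- fit_selection_coefficient(tr_dn, z_wt, c(zb, 0.05))
  expect_equal(fit_dn$s, 0.067, tolerance = 0.01)
  # Monte-Carlo bias under 5% observation noise stays below 5%
  s_hat <- vapply(1:30, function(sd) {
    tri <- generate_trajectory(0.055, 1e-7, z_wt, c(1, 1),
                               obs_noise_cv = 0.05, seed = sd)
    fit_selection_coefficient(tri, z_wt, c(1, 1))$s
  }, numeric(1))
  expect_lt(abs(mean(s_hat) / 0.055 - 1), 0.05)
  # tidiers expose the profile half-width
  expect_true(is.finite(glance(fit)$s_half_width))
  expect_equal(tidy(fit)$term, c("s", "x0"))
})

test_that("flat trajectories are rejected as non-identifiable", {
  zb <- 0.005
  tr0 <- generate_trajectory(1e-9, 1e-7, c(zb, 1), c(1, 1),
                             obs_noise_cv = 0, seed = 1)
  expect_error(fit_selection_coefficient(tr0, c(zb, 1), c(1, 1)),
               "Non-identifiable")
  # genotypes identical in both assays: nothing to fit either
  tr1 <- generate_trajectory(0.05, 1e-7, c(zb, 1), c(zb, 1),
                             obs_noise_cv = 0, seed = 1)
  expect_error(fit_selection_coefficient(tr1, c(zb, 1), c(zb, 1)),
               "Non-identifiable")
})

test_that("neutral fixation time is the inverse mutation rate", {
  expect_identical(neutral_fixation_time(1e-6), 1e6)
  expect_identical(neutral_fixation_time(0.01), 100)
  expect_identical(neutral_fixation_time(1), 1)
  expect_error(neutral_fixation_time(0), "positive")
})
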