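# Serial-dilution evolution: logistic sweeps, a grow-dilute simulator, and a
# competition-model fitter for selection coefficients.
#
# Selection-coefficient convention (per generation, generations counted for
# the reference genotype): odds(t+1)/odds(t) = 1 + s, which maps to growth
# rates as 1 + s = 2^((g_mut - g_ref)/g_ref).

#' Mutant frequency under a constant selection coefficient
#'
#' Closed-form logistic-in-odds sweep:
#' `odds(t) = odds(0) * (1 + s)^t`, `x(t) = odds / (1 + odds)`. Equivalent to
#' iterating the per-generation map `x <- x (1 + s) / (1 + s x)`.
#'
#' @param s Selection coefficient per generation (> -1).
#' @param x0 Initial mutant frequency, in (0, 1).
#' @param t Generations (>= 0), vectorized.
#' @return Mutant frequency (or frequencies) at `t`.
#' @examples
#' mutant_frequency(0.055, 1e-7, 301)  # ~0.5: a ~300-generation sweep
#' @export
mutant_frequency <- function(s, x0, t) {
  if (s <= -1) abort("`s` must exceed -1.")
  if (!(x0 > 0 && x0 < 1)) abort("`x0` must lie strictly between 0 and 1.")
  if (any(t < 0)) abort("`t` must be nonnegative.")
  log_odds <- log(x0) - log1p(-x0) + t * log1p(s)
  stats::plogis(log_odds)
}

#' Competing genotype
#'
#' A genotype is the wild-type growth model with its regulatory response (and
#' optionally cost/benefit) replaced. A constitutive (lacI-null) mutant, for
#' example, has `z_basal` raised to `z_max`.
#'
#' @param label Genotype name.
#' @param induction A [lac_induction_params()] object.
#' @param cost,benefit Optional [lac_cost_params()] / [lac_benefit_params()]
#'   overrides; `NULL` inherits from the base model.
#' @return An object of class `lac_genotype`.
#' @examples
#' wt <- lac_genotype("wt", lac_default_params()$induction)
#' con <- constitutive_genotype(lac_default_params())
#' @export
lac_genotype <- function(label, induction, cost = NULL, benefit = NULL) {
  stopifnot(is.character(label), length(label) == 1)
  if (!inherits(induction, "lac_induction_params"))
    abort("`induction` must be a `lac_induction_params` object.")
  if (!is.null(cost) && !inherits(cost, "lac_cost_params"))
    abort("`cost` must be a `lac_cost_params` object or NULL.")
  if (!is.null(benefit) && !inherits(benefit, "lac_benefit_params"))
    abort("`benefit` must be a `lac_benefit_params` object or NULL.")
  structure(list(label = label, induction = induction, cost = cost,
                 benefit = benefit), class = "lac_genotype")
}

#' @rdname lac_genotype
#' @param model Base growth model whose induction parameters are made
#'   constitutive.
#' @export
constitutive_genotype <- function(model) {
  model <- as_growth_params(model)
  ip <- model$induction
  lac_genotype("constitutive",
               lac_induction_params(z_basal = ip$z_max * (1 - 1e-9),
                                    z_max = ip$z_max, k_half = ip$k_half,
                                    hill_n = ip$hill_n, k_anti = ip$k_anti))
}

genotype_params <- function(genotype, model) {
  # the cost reference stays at the wild-type basal level: a mutant that
  # raises its uninduced expression pays the corresponding cost
  lac_growth_params(g0 = model$g0, induction = genotype$induction,
                    cost = genotype$cost %||% model$cost,
                    benefit = genotype$benefit %||% model$benefit,
                    z_cost_ref = model$z_cost_ref %||% model$induction$z_basal)
}

#' Serial-transfer protocol
#'
#' @param dilution_factor Fold dilution per transfer (> 1; the study used
#'   300--500x). Generations per cycle = `log2(dilution_factor)`.
#' @param transfers_per_day Transfers per day (bookkeeping only).
#' @param culture_volume_ml Culture volume, ml.
#' @param stationary_density Stationary cell density, cells/ml.
#' @param bottleneck_mode `"deterministic"` (infinite-population frequencies)
#'   or `"binomial"` (multinomial resampling at each bottleneck plus
#'   stochastic mutant appearance).
#' @return An object of class `lac_transfer_protocol`.
#' @export
lac_transfer_protocol <- function(dilution_factor = 400,
                                  transfers_per_day = 2,
                                  culture_volume_ml = 10,
                                  stationary_density = 1e9,
                                  bottleneck_mode = c("deterministic",
                                                      "binomial")) {
  bottleneck_mode <- arg_match(bottleneck_mode)
  if (!(dilution_factor > 1)) abort("`dilution_factor` must exceed 1.")
  stopifnot(culture_volume_ml > 0, stationary_density > 0)
  structure(list(dilution_factor = dilution_factor,
                 transfers_per_day = transfers_per_day,
                 culture_volume_ml = culture_volume_ml,
                 stationary_density = stationary_density,
                 bottleneck_mode = bottleneck_mode),
            class = "lac_transfer_protocol")
}

generations_per_cycle <- function(protocol) log2(protocol$dilution_factor)

bottleneck_size <- function(protocol) {
  protocol$stationary_density * protocol$culture_volume_ml /
    protocol$dilution_factor
}

#' Environment schedule for serial transfer
#'
#' A cyclic list of (IPTG, Pgal) conditions, each held for a number of
#' transfer cycles. A constant environment is a single entry.
#'
#' @param iptg,pgal Concentrations (uM), recycled to equal length.
#' @param cycles Transfer cycles spent in each entry before moving on.
#' @return A tibble of class `lac_schedule` with columns `iptg`, `pgal`,
#'   `cycles`.
#' @export
lac_schedule <- function(iptg, pgal, cycles = 1) {
  n <- max(length(iptg), length(pgal), length(cycles))
  iptg <- rep_len(iptg, n); pgal <- rep_len(pgal, n)
  cycles <- rep_len(cycles, n)
  if (any(iptg < 0) || any(pgal < 0)) abort("Concentrations must be nonnegative.")
  if (any(cycles < 1)) abort("`cycles` must be >= 1.")
  structure(tibble(iptg = iptg, pgal = pgal, cycles = cycles),
            class = c("lac_schedule", class(tibble())))
}

# expand a schedule to one environment row per transfer cycle
schedule_cycle_env <- function(schedule, n_cycles) {
  reps <- tidyr::uncount(as_tibble(schedule), .data$cycles)
  idx <- ((seq_len(n_cycles) - 1) %% nrow(reps)) + 1
  reps[idx, c("iptg", "pgal")]
}

#' Simulate serial-dilution evolution
#'
#' Grow-dilute dynamics for competing genotypes. Within each transfer cycle
#' every genotype grows exponentially at its own model growth rate for the
#' cycle's duration; the cycle lasts `log2(dilution_factor)` generations of
#' the first (reference) genotype. In `"binomial"` mode the population is
#' resampled multinomially at each bottleneck and reference-to-mutant
#' conversions are injected stochastically at `mutation_rate` per cell
#' division. The emitted trajectory records population-mean expression under
#' the two assay conditions (uninduced: 0 uM IPTG; induced: 220 uM IPTG, both
#' without Pgal).
#'
#' @param genotypes List of [lac_genotype()] objects; the first is the
#'   reference (wild type) that defines the generation clock and is the
#'   source of new mutants.
#' @param freqs0 Initial frequencies (summing to 1).
#' @param schedule A [lac_schedule()].
#' @param protocol A [lac_transfer_protocol()].
#' @param model Base [lac_growth_params()] supplying everything a genotype
#'   does not override.
#' @param mutation_rate Reference-to-mutant conversion rate per cell per
#'   generation (binomial mode only).
#' @param n_generations Total generations to simulate.
#' @param seed Integer seed (binomial mode).
#' @param assay_iptg Length-2 vector of assay IPTG concentrations
#'   `c(uninduced, induced)`.
#' @return A tibble of class `lac_trajectory` with columns `generation`,
#'   `expr_uninduced`, `expr_induced`, `freq_mutant` (total non-reference
#'   frequency), plus one `freq_<label>` column per genotype. The attribute
#'   `truncated` flags an all-lineage extinction in binomial mode.
#' @export
simulate_serial_transfer <- function(genotypes, freqs0, schedule, protocol,
                                     model, mutation_rate = 0,
                                     n_generations, seed = 1,
                                     assay_iptg = c(0, 220)) {
  if (inherits(genotypes, "lac_genotype")) genotypes <- list(genotypes)
  stopifnot(length(genotypes) >= 1, n_generations > 0)
  if (abs(sum(freqs0) - 1) > 1e-8) abort("`freqs0` must sum to 1.")
  if (length(freqs0) != length(genotypes))
    abort("`freqs0` must match `genotypes` in length.")
  model <- as_growth_params(model)
  plist <- map(genotypes, genotype_params, model = model)
  labels <- map(genotypes, "label")
  # assay expression of each genotype, fixed over time
  z_unind <- map_dbl(plist, function(p) induction_response(assay_iptg[1], 0, p))
  z_ind <- map_dbl(plist, function(p) induction_response(assay_iptg[2], 0, p))

  gpc <- generations_per_cycle(protocol)
  n_cycles <- ceiling(n_generations / gpc)
  envs <- schedule_cycle_env(schedule, n_cycles)
  n_b <- round(bottleneck_size(protocol))
  binom <- protocol$bottleneck_mode == "binomial"
  n_stat <- protocol$stationary_density * protocol$culture_volume_ml

  run <- function() {
    freq <- freqs0
    truncated <- FALSE
    out <- vector("list", n_cycles + 1)
    record <- function(gen, freq) {
      tibble(generation = gen,
             expr_uninduced = sum(freq * z_unind),
             expr_induced = sum(freq * z_ind),
             freq_mutant = 1 - freq[1],
             !!!setNames(as.list(freq), paste0("freq_", labels)))
    }
    out[[1]] <- record(0, freq)
    for (cyc in seq_len(n_cycles)) {
      I <- envs$iptg[cyc]; P <- envs$pgal[cyc]
      g <- map_dbl(plist, function(p) growth_rate(I, P, p))
      t_hr <- gpc / g[1]              # cycle duration on the reference clock
      grown <- freq * 2^(g * t_hr)
      freq <- grown / sum(grown)
      if (binom) {
        # mutant supply: conversions during the cycle's reference divisions
        if (mutation_rate > 0 && freq[1] > 0 && length(freq) > 1) {
          n_div <- n_stat * freq[1]
          k <- rpois(1, mutation_rate * n_div)
          dx <- min(k / n_stat, freq[1])
          freq[1] <- freq[1] - dx
          freq[-1] <- freq[-1] + dx / (length(freq) - 1)
        }
        counts <- as.vector(rmultinom(1, size = n_b, prob = freq))
        if (sum(counts) == 0) { truncated <- TRUE; break }
        freq <- counts / sum(counts)
      }
      out[[cyc + 1]] <- record(cyc * gpc, freq)
    }
    traj <- list_rbind(out[!vapply(out, is.null, logical(1))])
    structure(traj, truncated = truncated,
              class = c("lac_trajectory", class(tibble())))
  }

  if (binom) withr::with_seed(seed, run()) else run()
}

#' Fit a single-sweep competition model to an expression trajectory
#'
#' Least-squares fit of
#' `expr_c(t) = x(t) z_mut[c] + (1 - x(t)) z_wt[c]` with
#' `x(t) = mutant_frequency(s, x0, t)`, jointly over the uninduced and
#' induced assay channels, estimating the selection coefficient `s` and the
#' initial frequency `x0`. Assumes a single sweeping mutant class. The
#' confidence half-width on `s` is profile-based: `x0` is re-optimized at
#' each trial `s` and the 95% sum-of-squares threshold is inverted.
#'
#' @param traj A trajectory tibble with columns `generation`,
#'   `expr_uninduced`, `expr_induced` (either may be all-`NA`).
#' @param z_wt,z_mut Length-2 vectors `c(uninduced, induced)` of genotype
#'   expression levels. Downward sweeps (`z_mut < z_wt`) are supported.
#' @return An object of class `lac_selection_fit` with elements `s`, `x0`,
#'   `residual_rms`, `s_half_width`, `converged`, `n_obs`, `fitted` (a
#'   tibble of fitted values).
#' @examples
#' tr <- generate_trajectory(0.055, 1e-7, z_wt = c(0.005, 1),
#'                           z_mut = c(1, 1), obs_noise_cv = 0, seed = 1)
#' fit_selection_coefficient(tr, z_wt = c(0.005, 1), z_mut = c(1, 1))$s
#' @export
fit_selection_coefficient <- function(traj, z_wt, z_mut) {
  stopifnot(length(z_wt) == 2, length(z_mut) == 2)
  need <- c("generation", "expr_uninduced", "expr_induced")
  if (!all(need %in% names(traj)))
    abort("`traj` must have columns generation, expr_uninduced, expr_induced.")
  t_obs <- traj$generation
  dz <- z_mut - z_wt
  obs <- cbind(traj$expr_uninduced, traj$expr_induced)
  use <- which(abs(dz) > 1e-12 & colSums(!is.na(obs)) > 0)
  if (!length(use))
    abort("Non-identifiable: no assay channel distinguishes the genotypes.")
  # a channel is informative if its range clears its own noise floor,
  # estimated from first differences (robust to the sweep's slow trend)
  informative <- map_dbl(use, function(j) {
    y <- obs[!is.na(obs[, j]), j]
    noise <- stats::mad(diff(y)) / sqrt(2)
    diff(range(y)) - max(5 * noise, 1e-12)
  })
  if (all(informative <= 0))
    abort("Non-identifiable: trajectory is flat relative to its noise level.")

  resid_fun <- function(u, v) {
    # u = log(1 + s), v = log-odds of x0
    x <- stats::plogis(v + t_obs * u)
    r <- unlist(lapply(use, function(j) {
      pred <- x * z_mut[j] + (1 - x) * z_wt[j]
      (obs[, j] - pred)[!is.na(obs[, j])]
    }))
    r
  }
  ssq <- function(par) sum(resid_fun(par[1], par[2])^2)

  starts <- tidyr::expand_grid(s = c(0.01, 0.03, 0.06, 0.12),
                               x0 = c(1e-7, 1e-4, 1e-2))
  fits <- pmap(starts, function(s, x0)
    optim(c(log1p(s), log(x0 / (1 - x0))), ssq, method = "Nelder-Mead",
          control = list(maxit = 500, reltol = 1e-14)))
  best <- fits[[which.min(map_dbl(fits, "value"))]]
  u_hat <- best$par[1]; v_hat <- best$par[2]
  s_hat <- expm1(u_hat); x0_hat <- stats::plogis(v_hat)
  n_obs <- length(resid_fun(u_hat, v_hat))
  df <- max(n_obs - 2, 1)
  ssq_min <- best$value
  sigma2 <- ssq_min / df
  # profile on u: re-optimize v at each trial u
  prof <- function(u) optimize(function(v) sum(resid_fun(u, v)^2),
                               v_hat + c(-25, 25), tol = 1e-12)$objective
  thr <- ssq_min + sigma2 * qf(0.95, 1, df)
  half <- tryCatch({
    lo <- uniroot(function(u) prof(u) - thr, c(u_hat - 1, u_hat),
                  tol = 1e-9)$root
    hi <- uniroot(function(u) prof(u) - thr, c(u_hat, u_hat + 1),
                  tol = 1e-9)$root
    (expm1(hi) - expm1(lo)) / 2
  }, error = function(e) NA_real_)

  x_fit <- stats::plogis(v_hat + t_obs * u_hat)
  fitted <- tibble(generation = t_obs,
                   freq_mutant = x_fit,
                   expr_uninduced = x_fit * z_mut[1] + (1 - x_fit) * z_wt[1],
                   expr_induced = x_fit * z_mut[2] + (1 - x_fit) * z_wt[2])
  structure(list(s = s_hat, x0 = x0_hat,
                 residual_rms = sqrt(ssq_min / n_obs),
                 s_half_width = half,
                 converged = best$convergence == 0,
                 n_obs = n_obs, fitted = fitted,
                 z_wt = z_wt, z_mut = z_mut),
            class = "lac_selection_fit")
}

#' @export
print.lac_selection_fit <- function(x, ...) {
  cat(sprintf("<lac_selection_fit> s = %.4g (+/- %.2g), x0 = %.3g, RMS = %.3g, n = %d\n",
              x$s, x$s_half_width, x$x0, x$residual_rms, x$n_obs))
  invisible(x)
}

#' Neutral-drift fixation timescale
#'
#' The expected number of generations before a selectively neutral mutant
#' class arising at rate `mutation_rate` per cell per generation fixes:
#' `1 / mutation_rate`. At the lacI-null mutation rate of ~1e-6 this is 1e6
#' generations, far beyond a serial-transfer experiment.
#'
#' @param mutation_rate Per cell per generation (> 0).
#' @return Generations.
#' @export
neutral_fixation_time <- function(mutation_rate) {
  if (!(is.numeric(mutation_rate) && all(mutation_rate > 0)))
    abort("`mutation_rate` must be positive.")
  1 / mutation_rate
}
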