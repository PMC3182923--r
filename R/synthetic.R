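# Synthetic-data generators: every input the pipeline consumes can be produced
# from a calibrated ground truth plus a seed, so the whole analysis is testable
# without external data.

#' Printed anchor values for calibration
#'
#' The published quantities the calibrated ground truth must reproduce: basal
#' growth rate 1.09 doublings/hr; full-induction cost 0.2 doublings/hr;
#' maximal net Pgal-driven increase 1.6 doublings/hr (full induction, 500 uM
#' Pgal); cost-benefit balance at 120 uM Pgal under 220 uM IPTG; optimal IPTG
#' of 5 uM at 100 uM Pgal and 30 uM at 240 uM Pgal; optimal-expression
#' inflection near 150 uM Pgal; anti-induction scale 1000 uM (from the ~1 mM
#' repressor-Pgal dissociation constant); and a 4.3% relative measurement
#' error.
#'
#' @return A named list of anchor values (class `lac_anchors`).
#' @export
lac_anchors <- function() {
  structure(list(
    g0 = 1.09,
    full_induction_cost = 0.2,
    max_net_increase = 1.6,
    max_net_increase_pgal = 500,
    balance_pgal = 120,
    balance_iptg = 220,
    i_opt = c("100" = 5, "240" = 30),
    zopt_inflection = 150,
    k_anti = 1000,
    noise_cv = 0.043
  ), class = "lac_anchors")
}

# ---- fast internal anchor evaluators (used inside the calibration objective;
#      final residuals are recomputed with the public operations) ----

# optimal expression by inverting the marginal condition; a <= 1 only
.zopt_fast <- function(P, v) {
  fp <- 1 / (1 + (v[["k_pgal"]] / P)^v[["hill_p"]])
  a <- v[["z_exponent"]]; zb <- v[["z_basal"]]; zm <- v[["z_max"]]
  m <- v[["m_sat"]]; c0 <- v[["eta0"]] * (1 - zb / m)
  slope <- function(Z) a * v[["delta"]] * Z^(a - 1) * fp - c0 / (1 - Z / m)^2
  lo <- max(zb, 1e-12)
  if (slope(lo) <= 0) return(zb)
  if (slope(zm) >= 0) return(zm)
  uniroot(slope, c(lo, zm), tol = 1e-11)$root
}

.iopt_fast <- function(P, v) {
  z <- .zopt_fast(P, v)
  zb <- v[["z_basal"]]; zm <- v[["z_max"]]
  r <- (z - zb) / (zm - zb)
  if (r <= 0) return(0)
  if (r >= 1 - 1e-10) return(Inf)
  k_eff <- v[["k_half"]] * (1 + P / v[["k_anti"]])
  k_eff * (r / (1 - r))^(1 / v[["hill_n"]])
}

# parametric inflection: along the interior branch the marginal condition
# gives P(Z) in closed form, so dZ_opt/dP is available without optimization
.inflection_fast <- function(v, p_limit = 500) {
  zb <- v[["z_basal"]]; zm <- v[["z_max"]]; m <- v[["m_sat"]]
  a <- v[["z_exponent"]]; c0 <- v[["eta0"]] * (1 - zb / m)
  Z <- seq(zb + 1e-6, zm - 1e-9, length.out = 400)
  phi <- c0 / ((1 - Z / m)^2 * a * v[["delta"]] * Z^(a - 1))
  ok <- phi > 0 & phi < 1
  if (sum(ok) < 5) return(NA_real_)
  P <- v[["k_pgal"]] * (phi[ok] / (1 - phi[ok]))^(1 / v[["hill_p"]])
  Z <- Z[ok]
  keep <- P > 0 & P <= p_limit
  if (sum(keep) < 5) return(NA_real_)
  P <- P[keep]; Z <- Z[keep]
  dz <- diff(Z) / diff(P)
  Pm <- (P[-1] + P[-length(P)]) / 2
  Pm[which.max(dz)]
}

.balance_fast <- function(I, v, params) {
  h <- function(P) growth_rate(I, P, params) - params$g0
  grid <- 10^seq(0, 4, length.out = 120)
  hv <- vapply(grid, h, numeric(1))
  idx <- which(hv[-1] > 0 & hv[-length(hv)] <= 0)
  if (!length(idx)) return(NA_real_)
  uniroot(h, c(grid[idx[1]], grid[idx[1] + 1]), tol = 1e-7)$root
}

.calib_free_default <- c("eta0", "m_sat", "delta", "k_pgal", "hill_p",
                         "k_half", "hill_n", "z_basal", "z_exponent")

# starting point for calibration: chosen by a coarse feasibility scan of the
# model family (see the methods vignette)
.calib_init <- function(anchors) {
  c(g0 = anchors$g0, z_basal = 0.005, z_max = 1, k_half = 12.9, hill_n = 1.58,
    k_anti = anchors$k_anti, eta0 = 0.134, m_sat = 3, delta = 2.22,
    k_pgal = 383, hill_p = 2, z_exponent = 0.3)
}

.calib_transform <- function(v, free) {
  th <- log(v[free])
  th["m_sat"] <- if ("m_sat" %in% free) log(v[["m_sat"]] - v[["z_max"]]) else th["m_sat"]
  th[free]
}

.calib_untransform <- function(th, v0, free) {
  v <- v0
  v[free] <- exp(th)
  if ("m_sat" %in% free) v[["m_sat"]] <- v[["z_max"]] + exp(th[["m_sat"]])
  v
}

#' Calibrate the ground-truth growth model to the printed anchors
#'
#' Minimizes the sum of squared relative mismatches between the model's
#' derived quantities and the anchor values of [lac_anchors()], over the free
#' parameters, with `g0` and `k_anti` held fixed. A small ridge penalty toward
#' the starting point keeps the under-determined system well posed, and a
#' seeded Latin-hypercube multistart guards against local optima. Residuals
#' are recomputed with the public operations ([expression_cost()],
#' [balance_concentration()], [optimal_inducer()], [optimality_curve()])
#' before being reported.
#'
#' @param anchors A [lac_anchors()] object.
#' @param free Names of the parameters allowed to vary.
#' @param seed Integer seed controlling the multistart perturbations.
#' @param n_starts Number of multistarts (the first starts at the built-in
#'   initial point).
#' @param maxit Nelder-Mead iteration budget per start.
#' @param tol Largest acceptable absolute relative residual per anchor;
#'   exceeding it is a calibration failure naming the offending anchor.
#' @return An object of class `lac_ground_truth`: a list with elements
#'   `model` ([lac_growth_params()]), `noise_cv`, and `residuals` (a tibble
#'   with one row per anchor).
#' @export
calibrate_ground_truth <- function(anchors = lac_anchors(),
                                   free = .calib_free_default,
                                   seed = 1, n_starts = 6, maxit = 400,
                                   tol = 0.15) {
  stopifnot(inherits(anchors, "lac_anchors"))
  bad <- setdiff(free, .calib_free_default)
  if (length(bad)) abort(paste0("Unknown free parameter(s): ",
                                paste(bad, collapse = ", ")))
  v0 <- .calib_init(anchors)
  th0 <- .calib_transform(v0, free)

  objective <- function(th) {
    v <- tryCatch(.calib_untransform(setNames(th, free), v0, free),
                  error = function(e) NULL)
    if (is.null(v) || !all(is.finite(v))) return(1e6)
    if (v[["z_exponent"]] > 1 || v[["z_basal"]] >= 0.5 * v[["z_max"]] ||
        v[["m_sat"]] <= v[["z_max"]] * 1.01)
      return(1e6)
    params <- tryCatch(vec_to_params(v), error = function(e) NULL)
    if (is.null(params)) return(1e6)
    res <- .anchor_residuals_fast(v, params, anchors)
    if (any(!is.finite(res))) return(1e6)
    sum(res^2) + 1e-3 * sum((th - th0)^2)
  }

  starts <- list(th0)
  if (n_starts > 1) {
    pert <- withr::with_seed(seed, lhs::randomLHS(n_starts - 1, length(free)))
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- th0 + (pert[i, ] - 0.5) * 0.4
  }
  fits <- map(starts, function(s)
    optim(s, objective, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-12)))
  best <- fits[[which.min(map_dbl(fits, "value"))]]
  v <- .calib_untransform(setNames(best$par, free), v0, free)
  model <- vec_to_params(v)

  res <- .anchor_residuals_public(model, anchors)
  offending <- res$anchor[abs(res$rel_residual) > tol]
  if (length(offending))
    abort(paste0("Calibration failure: anchor(s) beyond ", tol * 100,
                 "% relative: ", paste(offending, collapse = ", ")))
  structure(list(model = model, noise_cv = anchors$noise_cv,
                 residuals = res, objective = best$value),
            class = "lac_ground_truth")
}

.anchor_residuals_fast <- function(v, params, anchors) {
  cost1 <- expression_cost(1, params)
  bal <- .balance_fast(anchors$balance_iptg, v, params)
  net <- growth_rate(220, anchors$max_net_increase_pgal, params) -
    growth_rate(220, 0, params) + cost1
  i100 <- .iopt_fast(as.numeric(names(anchors$i_opt)[1]), v)
  i240 <- .iopt_fast(as.numeric(names(anchors$i_opt)[2]), v)
  infl <- .inflection_fast(v)
  c(cost1 / anchors$full_induction_cost - 1,
    bal / anchors$balance_pgal - 1,
    net / anchors$max_net_increase - 1,
    i100 / anchors$i_opt[[1]] - 1,
    i240 / anchors$i_opt[[2]] - 1,
    infl / anchors$zopt_inflection - 1)
}

.anchor_residuals_public <- function(model, anchors) {
  cost1 <- expression_cost(1, model)
  bal <- tryCatch(balance_concentration(anchors$balance_iptg, model),
                  error = function(e) NA_real_)
  net <- growth_rate(220, anchors$max_net_increase_pgal, model) -
    growth_rate(220, 0, model) + cost1
  iopts <- optimal_inducer(as.numeric(names(anchors$i_opt)), model)
  infl <- tryCatch(
    lac_inflection(optimality_curve(seq(1, 500, length.out = 60), model)),
    error = function(e) NA_real_)
  tibble(
    anchor = c("g0", "full_induction_cost", "balance_pgal",
               "max_net_increase", "i_opt_100", "i_opt_240",
               "zopt_inflection"),
    target = c(anchors$g0, anchors$full_induction_cost, anchors$balance_pgal,
               anchors$max_net_increase, anchors$i_opt[[1]],
               anchors$i_opt[[2]], anchors$zopt_inflection),
    achieved = c(model$g0, cost1, bal, net, iopts[1], iopts[2], infl)
  ) |>
    mutate(rel_residual = (.data$achieved - .data$target) / .data$target)
}

#' @export
print.lac_ground_truth <- function(x, ...) {
  cat("<lac_ground_truth> calibrated growth model + noise model\n")
  print(x$model)
  cat(sprintf("  noise_cv %.3f\n", x$noise_cv))
  cat("  anchor residuals:\n")
  print(as.data.frame(x$residuals), row.names = FALSE, digits = 3)
  invisible(x)
}

.default_iptg_levels <- c(0, 2, 5, 15, 30, 50, 220)
.default_pgal_levels <- c(0, 39, 100, 240, 350, 500)

truth_model <- function(truth) {
  if (inherits(truth, "lac_ground_truth")) truth$model
  else as_growth_params(truth)
}

truth_noise <- function(truth) {
  if (inherits(truth, "lac_ground_truth")) truth$noise_cv
  else lac_default_noise_cv()
}

#' Generate a replicated synthetic growth grid
#'
#' Emulates plate-reader growth-rate determinations over an (IPTG, Pgal)
#' condition grid: the model growth rate times independent multiplicative
#' Gaussian noise, `g * (1 + e)`, `e ~ N(0, noise_cv)`, per replicate.
#'
#' @param truth A `lac_ground_truth` (or bare [lac_growth_params()], in which
#'   case the default 4.3% noise is used).
#' @param iptg_levels,pgal_levels Condition grids (uM). Defaults mirror the
#'   concentrations named in the study: IPTG 0--220 uM, Pgal 0--500 uM.
#' @param replicates Replicates per condition (>= 1).
#' @param seed Integer seed.
#' @param noise_cv Override of the noise coefficient of variation.
#' @return A growth-grid tibble with columns `iptg`, `pgal`, `replicate`,
#'   `growth` (doublings/hr).
#' @export
generate_growth_grid <- function(truth,
                                 iptg_levels = .default_iptg_levels,
                                 pgal_levels = .default_pgal_levels,
                                 replicates = 3, seed = 1,
                                 noise_cv = NULL) {
  model <- truth_model(truth)
  cv <- noise_cv %||% truth_noise(truth)
  if (replicates < 1) abort("`replicates` must be >= 1.")
  grid <- tidyr::expand_grid(pgal = pgal_levels, iptg = iptg_levels,
                             replicate = seq_len(replicates))
  mu <- growth_rate(grid$iptg, grid$pgal, model)
  eps <- withr::with_seed(seed, rnorm(nrow(grid), 0, cv))
  grid |>
    mutate(growth = mu * (1 + eps)) |>
    arrange(.data$pgal, .data$iptg, .data$replicate) |>
    dplyr::select("iptg", "pgal", "replicate", "growth")
}

#' Generate a synthetic OD600 growth curve
#'
#' Exponential growth `OD(t) = od0 * 2^(g t)` capped at a stationary plateau,
#' sampled every `dt_min` minutes with multiplicative noise.
#'
#' @param growth Growth rate, doublings/hr.
#' @param od0 Inoculation density (default 5e-4, the study's dilution target).
#' @param duration_hr Total duration, hours.
#' @param dt_min Sampling interval, minutes (default 4).
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param plateau_od Stationary-phase ceiling.
#' @param well Well identifier.
#' @return A plate time-series tibble (`well`, `channel`, `time_min`, `value`).
#' @export
generate_od_curve <- function(growth, od0 = 5e-4, duration_hr = 12,
                              dt_min = 4, noise_cv = 0.02, seed = 1,
                              plateau_od = 0.5, well = "A1") {
  stopifnot(growth > 0, od0 > 0, duration_hr > 0, dt_min > 0)
  t_min <- seq(0, duration_hr * 60, by = dt_min)
  od <- pmin(od0 * 2^(growth * t_min / 60), plateau_od)
  eps <- withr::with_seed(seed, rnorm(length(od), 0, noise_cv))
  tibble(well = well, channel = "od600", time_min = t_min,
         value = pmax(od * (1 + eps), 0))
}

#' Generate a synthetic FDG fluorescence curve
#'
#' A sigmoidal fluorescence accumulation whose maximum slope is proportional
#' to the LacZ activity, so the assay reduction
#' ([lacz_activity_from_fdg()]) is linear in activity over arbitrarily many
#' orders of magnitude.
#'
#' @param activity Relative LacZ activity (>= 0); 0 yields a flat curve.
#' @param duration_hr Duration, hours.
#' @param dt_min Sampling interval, minutes.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param tau_min Time constant of the sigmoid, minutes.
#' @param well Well identifier.
#' @return A plate time-series tibble (`well`, `channel`, `time_min`, `value`).
#' @export
generate_fdg_curve <- function(activity, duration_hr = 6, dt_min = 4,
                               noise_cv = 0.02, seed = 1, tau_min = 30,
                               well = "A1") {
  stopifnot(activity >= 0, duration_hr > 0, dt_min > 0)
  t_min <- seq(0, duration_hr * 60, by = dt_min)
  t0 <- duration_hr * 60 / 2
  f <- activity * 4 * tau_min / (1 + exp(-(t_min - t0) / tau_min))
  eps <- withr::with_seed(seed, rnorm(length(f), 0, noise_cv))
  tibble(well = well, channel = "fdg", time_min = t_min,
         value = pmax(f * (1 + eps), 0))
}

#' Generate a synthetic mutant-sweep expression trajectory
#'
#' A deterministic logistic sweep [mutant_frequency()] mixed into
#' population-mean expression under the two assay conditions, with
#' multiplicative observation noise: emulates population-average expression
#' trajectories sampled over generations during serial-transfer evolution.
#'
#' @param s Per-generation selection coefficient of the sweeping mutant.
#' @param x0 Initial mutant frequency.
#' @param z_wt,z_mut Length-2 vectors `c(uninduced, induced)` of expression
#'   fractions for the two genotypes.
#' @param n_gen Total generations simulated.
#' @param sample_every Sampling interval, generations.
#' @param obs_noise_cv Multiplicative observation noise CV.
#' @param seed Integer seed.
#' @return A tibble of class `lac_trajectory` with columns `generation`,
#'   `expr_uninduced`, `expr_induced`.
#' @export
generate_trajectory <- function(s, x0, z_wt, z_mut, n_gen = 800,
                                sample_every = 25, obs_noise_cv = 0.05,
                                seed = 1) {
  stopifnot(length(z_wt) == 2, length(z_mut) == 2, n_gen > 0,
            sample_every > 0)
  gens <- seq(0, n_gen, by = sample_every)
  x <- mutant_frequency(s, x0, gens)
  eu <- x * z_mut[1] + (1 - x) * z_wt[1]
  ei <- x * z_mut[2] + (1 - x) * z_wt[2]
  eps <- withr::with_seed(seed, rnorm(2 * length(gens), 0, obs_noise_cv))
  structure(
    tibble(generation = gens,
           expr_uninduced = eu * (1 + eps[seq_along(gens)]),
           expr_induced = ei * (1 + eps[length(gens) + seq_along(gens)])),
    class = c("lac_trajectory", class(tibble())))
}
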