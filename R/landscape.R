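# Growth-landscape analysis: fitting the cost-benefit model to replicated
# growth grids, empirical optima, smoothed interpolation, and cross-environment
# tradeoff (Pareto front) analysis.

validate_growth_grid <- function(grid, arg = "grid") {
  need <- c("iptg", "pgal", "replicate", "growth")
  if (!all(need %in% names(grid)))
    abort(paste0("`", arg, "` must have columns ",
                 paste(need, collapse = ", "), "."))
  if (any(grid$iptg < 0) || any(grid$pgal < 0))
    abort("Grid concentrations must be nonnegative.")
  if (any(!is.finite(grid$growth)) || any(grid$growth <= 0))
    abort("Grid growth rates must be finite and positive.")
  invisible(grid)
}

grid_condition_means <- function(grid) {
  grid |>
    group_by(.data$iptg, .data$pgal) |>
    summarise(mean_growth = mean(.data$growth),
              sd_growth = sd(.data$growth),
              n_rep = n(), .groups = "drop")
}

# per-condition weights from the replicate scatter: the relative error is
# pooled across conditions (per-condition SEMs from 2-3 replicates are too
# noisy to weight by directly) and scaled by each condition's mean and
# replicate count. Without replicates the pooled 4.3% error model is used.
condition_sigma <- function(means) {
  if (all(means$n_rep >= 2)) {
    cv <- sqrt(mean((means$sd_growth / means$mean_growth)^2, na.rm = TRUE))
    cv * means$mean_growth / sqrt(means$n_rep)
  } else {
    lac_default_noise_cv() * means$mean_growth / sqrt(means$n_rep)
  }
}

#' Fit the cost-benefit growth model to a growth grid
#'
#' Weighted least squares of the full decoupled model on replicate condition
#' means (weights from replicate SEMs, or the pooled 4.3% error model when
#' replicates are absent), via Levenberg-Marquardt with a seeded
#' Latin-hypercube multistart in log-transformed parameter space.
#'
#' @param grid A growth-grid tibble (`iptg`, `pgal`, `replicate`, `growth`);
#'   see [generate_growth_grid()] / [read_growth_grid()]. Needs at least 3
#'   IPTG and 3 Pgal levels.
#' @param init Starting [lac_growth_params()]; defaults to the calibrated set.
#' @param frozen Parameter names held at their `init` values. `z_max` is
#'   frozen by default: only products like `delta * z_max` are identifiable
#'   from growth data alone.
#' @param n_starts Multistart budget.
#' @param seed Seed for the multistart perturbations.
#' @return An object of class `lac_landscape_fit`: `params` (fitted
#'   [lac_growth_params()]), `residual_rms` (doublings/hr, on condition
#'   means), `conf` (tibble of per-parameter 95% half-widths from the fit
#'   curvature), `converged`, `data` (condition means used).
#' @export
fit_growth_model <- function(grid, init = lac_default_params(),
                             frozen = "z_max", n_starts = 16, seed = 1) {
  validate_growth_grid(grid)
  init <- as_growth_params(init)
  if (dplyr::n_distinct(grid$iptg) < 3 || dplyr::n_distinct(grid$pgal) < 3)
    abort("Degenerate grid: need at least 3 IPTG and 3 Pgal levels.")
  bad <- setdiff(frozen, PARAM_FIELDS)
  if (length(bad)) abort(paste0("Unknown parameter name(s) in `frozen`: ",
                                paste(bad, collapse = ", ")))
  free <- setdiff(PARAM_FIELDS, frozen)
  if (!length(free)) abort("All parameters frozen; nothing to fit.")

  means <- grid_condition_means(grid)
  sigma <- condition_sigma(means)
  v0 <- params_to_vec(init)
  form <- init$cost$form

  to_theta <- function(v) {
    th <- log(v[free])
    if ("m_sat" %in% free) th["m_sat"] <- log(v[["m_sat"]] - v[["z_max"]])
    th
  }
  from_theta <- function(th) {
    v <- v0
    v[free] <- exp(th)
    if ("m_sat" %in% free) v[["m_sat"]] <- v[["z_max"]] + exp(th[["m_sat"]])
    v
  }
  resid_fn <- function(th) {
    v <- from_theta(th)
    if (!all(is.finite(v)) || v[["z_basal"]] >= v[["z_max"]] ||
        (form == "saturating" && v[["m_sat"]] <= v[["z_max"]]))
      return(rep(1e4, nrow(means)))
    params <- tryCatch(vec_to_params(v, form = form), error = function(e) NULL)
    if (is.null(params)) return(rep(1e4, nrow(means)))
    pred <- growth_rate(means$iptg, means$pgal, params)
    (pred - means$mean_growth) / sigma
  }

  th0 <- to_theta(v0)
  starts <- list(th0)
  if (n_starts > 1) {
    pert <- withr::with_seed(seed, lhs::randomLHS(n_starts - 1, length(free)))
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- th0 + (pert[i, ] - 0.5) * 0.5
  }
  fits <- map(starts, function(s)
    tryCatch(minpack.lm::nls.lm(par = s, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500, ftol = 1e-11, ptol = 1e-10)),
             error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) abort("All multistarts failed.")
  dev <- map_dbl(fits, "deviance")
  best <- fits[[which.min(dev)]]
  converged <- best$info %in% 1:4
  if (!converged)
    warn(paste0("Growth-model fit did not converge after the multistart ",
                "budget (nls.lm info = ", best$info, "); result is flagged."))

  v_hat <- from_theta(best$par)
  params_hat <- vec_to_params(v_hat, form = form)
  pred <- growth_rate(means$iptg, means$pgal, params_hat)
  rrms <- sqrt(mean((pred - means$mean_growth)^2))

  # curvature-based half-widths, delta method through the log transform
  df <- max(nrow(means) - length(free), 1)
  sigma2 <- best$deviance / df
  half <- rep(NA_real_, length(free))
  # pseudo-inverse fallback: flat directions (e.g. m_sat escaping to the
  # linear-cost limit) make the curvature singular
  cov_th <- tryCatch(sigma2 * solve(best$hessian),
                     error = function(e) sigma2 * MASS::ginv(best$hessian))
  if (!is.null(cov_th)) {
    sd_th <- sqrt(pmax(diag(cov_th), 0))
    scale <- v_hat[free]
    if ("m_sat" %in% free)
      scale[["m_sat"]] <- v_hat[["m_sat"]] - v_hat[["z_max"]]
    half <- 1.96 * sd_th * scale
  }
  structure(list(
    params = params_hat,
    residual_rms = rrms,
    conf = tibble(term = free, estimate = unname(v_hat[free]),
                  half_width = unname(half)),
    converged = converged,
    frozen = frozen,
    n_conditions = nrow(means),
    data = means), class = "lac_landscape_fit")
}

#' @export
print.lac_landscape_fit <- function(x, ...) {
  cat(sprintf("<lac_landscape_fit> %d conditions, residual RMS %.4g dbl/hr, %s\n",
              x$n_conditions, x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Empirical optimal inducer per Pgal level
#'
#' For each Pgal row of a growth grid, the measured IPTG level with the
#' highest replicate-mean growth. Exact ties break toward lower IPTG
#' (expression is costly). Rows with fewer than 3 IPTG levels are skipped
#' with a warning.
#'
#' @param grid A growth-grid tibble.
#' @return A tibble with columns `pgal`, `iptg_opt`, `growth_opt`,
#'   `n_levels`.
#' @export
empirical_optima <- function(grid) {
  validate_growth_grid(grid)
  means <- grid_condition_means(grid)
  out <- means |>
    group_by(.data$pgal) |>
    summarise(n_levels = n(),
              growth_opt = max(.data$mean_growth),
              iptg_opt = min(.data$iptg[.data$mean_growth ==
                                          max(.data$mean_growth)]),
              .groups = "drop")
  skipped <- out$pgal[out$n_levels < 3]
  if (length(skipped))
    warn(paste0("Skipping Pgal row(s) with < 3 IPTG levels: ",
                paste(skipped, collapse = ", ")))
  out |>
    filter(.data$n_levels >= 3) |>
    dplyr::select("pgal", "iptg_opt", "growth_opt", "n_levels") |>
    arrange(.data$pgal)
}

#' Interpolated, smoothed growth landscape
#'
#' Thin-plate smooth of replicate-mean growth on `(log(1+I), log(1+P))`, the
#' coordinate system in which the condition grids are roughly regular. The
#' smoothing parameter is chosen by generalized cross-validation by default;
#' passing `smoothing = 0` gives exact interpolation of the condition means.
#'
#' @param grid A growth-grid tibble.
#' @param smoothing Smoothing parameter (`sp` of the thin-plate smooth);
#'   `NULL` (default) selects it by GCV.
#' @param allow_extrapolation Evaluate outside the convex hull of the
#'   measured conditions instead of erroring.
#' @return A function `f(I, P)` returning interpolated growth (doublings/hr),
#'   with the fitted smooth in attribute `"fit"`.
#' @export
interpolate_landscape <- function(grid, smoothing = NULL,
                                  allow_extrapolation = FALSE) {
  validate_growth_grid(grid)
  means <- grid_condition_means(grid)
  if (dplyr::n_distinct(means$iptg) < 3 || dplyr::n_distinct(means$pgal) < 3)
    abort("Degenerate grid: need at least 3 IPTG and 3 Pgal levels.")
  dat <- data.frame(li = log1p(means$iptg), lp = log1p(means$pgal),
                    g = means$mean_growth)
  k <- nrow(dat)
  fit <- mgcv::gam(g ~ s(li, lp, k = k), data = dat,
                   sp = if (is.null(smoothing)) NULL else smoothing)
  # convex hull, slightly inflated so boundary nodes evaluate cleanly
  hull <- dat[grDevices::chull(dat$li, dat$lp), c("li", "lp")]
  ctr <- colMeans(hull)
  hull <- sweep(sweep(as.matrix(hull), 2, ctr), 2, ctr, FUN = function(x, c) c + x * (1 + 1e-6))
  hull <- rbind(hull, hull[1, ])
  surface <- function(I, P) {
    n <- max(length(I), length(P))
    I <- rep_len(I, n); P <- rep_len(P, n)
    if (any(I < 0) || any(P < 0)) abort("Concentrations must be nonnegative.")
    pts <- cbind(log1p(I), log1p(P))
    if (!allow_extrapolation) {
      inside <- mgcv::in.out(hull, pts)
      if (!all(inside))
        abort(paste0("Point(s) outside the convex hull of measured ",
                     "conditions; set `allow_extrapolation = TRUE` to force."))
    }
    as.vector(predict(fit, data.frame(li = pts[, 1], lp = pts[, 2])))
  }
  attr(surface, "fit") <- fit
  surface
}

#' Cross-environment tradeoff curve (Pareto front)
#'
#' Growth in a high-Pgal environment versus growth in a low-Pgal environment
#' for phenotypes holding one constant inducer level -- the attainable set of
#' an unregulated phenotype. The "cross" is the pair of per-environment
#' optima that only a regulated phenotype can reach simultaneously. Also
#' reports the best constant inducer level for 50/50 time-averaged growth.
#'
#' @param params A [lac_growth_params()] object.
#' @param p_low,p_high Pgal concentrations (uM) of the two environments,
#'   `p_low < p_high`.
#' @param i_list Constant IPTG levels (uM) to tabulate; duplicates are
#'   dropped.
#' @return An object of class `lac_tradeoff`: `points` (tibble `iptg`,
#'   `g_low`, `g_high`), `cross` (named per-environment optima), and
#'   `best_constant` (list: `iptg`, `g_low`, `g_high`, `mean_growth`).
#' @export
tradeoff_curve <- function(params, p_low = 39, p_high = 500,
                           i_list = c(0, 2, 5, 15, 30, 50, 100, 220)) {
  params <- as_growth_params(params)
  if (!(p_low < p_high)) abort("`p_low` must be below `p_high`.")
  if (!length(i_list)) abort("`i_list` must be nonempty.")
  i_list <- sort(unique(i_list))
  points <- tibble(iptg = i_list,
                   g_low = growth_rate(i_list, p_low, params),
                   g_high = growth_rate(i_list, p_high, params))
  i_dense <- c(0, 10^seq(-2, log10(max(2000, 10 * max(i_list, 1))),
                         length.out = 600))
  gl <- growth_rate(i_dense, p_low, params)
  gh <- growth_rate(i_dense, p_high, params)
  cross <- c(g_low = max(gl, points$g_low), g_high = max(gh, points$g_high))
  avg <- (gl + gh) / 2
  ib <- which.max(avg)
  lo <- i_dense[max(1, ib - 1)]; hi <- i_dense[min(length(i_dense), ib + 1)]
  ob <- optimize(function(I) mean(growth_rate(I, c(p_low, p_high), params)),
                 c(lo, max(hi, lo + 1e-9)), maximum = TRUE, tol = 1e-8)
  best_i <- if (ob$objective >= avg[ib]) ob$maximum else i_dense[ib]
  structure(list(
    points = points, p_low = p_low, p_high = p_high, cross = cross,
    best_constant = list(iptg = best_i,
                         g_low = growth_rate(best_i, p_low, params),
                         g_high = growth_rate(best_i, p_high, params),
                         mean_growth = mean(growth_rate(best_i,
                                                        c(p_low, p_high),
                                                        params))),
    params = params), class = "lac_tradeoff")
}

#' @export
print.lac_tradeoff <- function(x, ...) {
  cat(sprintf("<lac_tradeoff> Pgal %g vs %g uM, %d constant-I points\n",
              x$p_low, x$p_high, nrow(x$points)))
  cat(sprintf("  cross (regulated): g_low = %.3f, g_high = %.3f dbl/hr\n",
              x$cross[["g_low"]], x$cross[["g_high"]]))
  cat(sprintf("  best constant I (50/50): %.3g uM, mean growth %.3f dbl/hr\n",
              x$best_constant$iptg, x$best_constant$mean_growth))
  invisible(x)
}

#' Selective advantage of regulation over the best constant phenotype
#'
#' Weighted-average growth at the cross (the regulated phenotype, optimal in
#' each environment) minus the best weighted-average growth attainable by any
#' tabulated constant-expression phenotype. Nonnegative by construction; zero
#' when some constant phenotype attains the cross.
#'
#' @param curve A [tradeoff_curve()] result.
#' @param weight_low Fraction of time spent in the low-Pgal environment
#'   (in `[0, 1]`).
#' @return Growth-rate advantage, doublings/hr.
#' @export
regulation_advantage <- function(curve, weight_low = 0.5) {
  stopifnot(inherits(curve, "lac_tradeoff"))
  if (!(weight_low >= 0 && weight_low <= 1))
    abort("`weight_low` must lie in [0, 1].")
  w <- weight_low
  cross_avg <- w * curve$cross[["g_low"]] + (1 - w) * curve$cross[["g_high"]]
  pt_avg <- w * curve$points$g_low + (1 - w) * curve$points$g_high
  cross_avg - max(pt_avg)
}

#' Concavity index of a tradeoff curve
#'
#' Maximal signed perpendicular elevation of the Pareto-front points above
#' the chord joining the two single-environment-optimal endpoints, normalized
#' by chord length. Positive values mean the front bulges toward the cross
#' (concave tradeoff), which limits the advantage of regulation.
#'
#' @param curve A [tradeoff_curve()] result with at least 3 points.
#' @return Dimensionless scalar; 0 (with a warning) for degenerate fronts.
#' @export
concavity_index <- function(curve) {
  stopifnot(inherits(curve, "lac_tradeoff"))
  pts <- curve$points
  if (nrow(pts) < 3) {
    warn("Fewer than 3 tradeoff points; concavity index set to 0.")
    return(0)
  }
  e_low <- pts |> arrange(dplyr::desc(.data$g_low), dplyr::desc(.data$g_high)) |> slice(1)
  e_high <- pts |> arrange(dplyr::desc(.data$g_high), dplyr::desc(.data$g_low)) |> slice(1)
  a <- c(e_low$g_low, e_low$g_high)
  b <- c(e_high$g_low, e_high$g_high)
  chord <- b - a
  len <- sqrt(sum(chord^2))
  if (len < 1e-12) {
    warn("Degenerate (zero-length) chord; concavity index set to 0.")
    return(0)
  }
  # Pareto front: non-dominated points
  nd <- vapply(seq_len(nrow(pts)), function(i) {
    !any(pts$g_low >= pts$g_low[i] & pts$g_high >= pts$g_high[i] &
           (pts$g_low > pts$g_low[i] | pts$g_high > pts$g_high[i]))
  }, logical(1))
  front <- pts[nd, ]
  normal <- c(-chord[2], chord[1]) / len
  cross_pt <- c(curve$cross[["g_low"]], curve$cross[["g_high"]])
  if (sum(normal * (cross_pt - (a + b) / 2)) < 0) normal <- -normal
  elev <- (front$g_low - a[1]) * normal[1] + (front$g_high - a[2]) * normal[2]
  max(elev) / len
}
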