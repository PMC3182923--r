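# Decoupled cost-benefit growth model:
#   g(I, P) = g0 - eta(Z_reg(I, P)) + B(Z_reg(I, P), P)
# I = IPTG (gratuitous inducer, uM), P = Pgal (non-inducing carbon source, uM),
# Z = lac operon expression normalized to the wild-type fully induced level.

as_growth_params <- function(params) {
  if (inherits(params, "lac_growth_params")) return(params)
  abort("`params` must be a `lac_growth_params` object (see `lac_growth_params()`).")
}

#' Regulatory response to inducer and anti-inducer
#'
#' Expression level `Z_reg(I, P)` of the lac operon: Hill induction by IPTG
#' with a half-point shifted by competitive anti-induction,
#' `Z = z_basal + (z_max - z_basal) * I^n / (K_eff^n + I^n)`,
#' `K_eff = k_half * (1 + P / k_anti)`.
#'
#' @param I IPTG concentration(s), uM (>= 0).
#' @param P Pgal concentration(s), uM (>= 0). Default 0.
#' @param params A [lac_induction_params()] or [lac_growth_params()] object.
#' @return Expression fraction(s) in `[z_basal, z_max]`.
#' @examples
#' p <- lac_induction_params(z_basal = 0, k_half = 6, hill_n = 2, k_anti = 1000)
#' induction_response(6, 0, p)   # half-maximal by construction
#' @export
induction_response <- function(I, P = 0, params) {
  ip <- if (inherits(params, "lac_growth_params")) params$induction else params
  if (!inherits(ip, "lac_induction_params"))
    abort("`params` must carry induction parameters.")
  if (any(I < 0) || any(P < 0))
    abort("Concentrations must be nonnegative.")
  n <- max(length(I), length(P))
  I <- rep_len(I, n); P <- rep_len(P, n)
  k_eff <- ip$k_half * (1 + P / ip$k_anti)
  frac <- ifelse(I == 0, 0, 1 / (1 + (k_eff / I)^ip$hill_n))
  ip$z_basal + (ip$z_max - ip$z_basal) * frac
}

#' Growth-rate cost of operon expression
#'
#' Saturating (default) form `eta(Z) = eta0 * (Z - z_basal) / (1 - Z / m_sat)`
#' or linear form `eta0 * (Z - z_basal)`; zero at basal expression.
#'
#' @param Z Expression fraction(s), `z_basal <= Z` (and `Z < m_sat` for the
#'   saturating form).
#' @param params A [lac_cost_params()] or [lac_growth_params()] object.
#' @param z_basal Reference basal expression; taken from the growth params
#'   when those are supplied, otherwise 0.
#' @return Growth-rate decrement(s), doublings/hr.
#' @export
expression_cost <- function(Z, params, z_basal = NULL) {
  if (inherits(params, "lac_growth_params")) {
    if (is.null(z_basal))
      z_basal <- params$z_cost_ref %||% params$induction$z_basal
    params <- params$cost
  }
  if (!inherits(params, "lac_cost_params"))
    abort("`params` must carry cost parameters.")
  if (is.null(z_basal)) z_basal <- 0
  if (any(Z < z_basal))
    abort("`Z` below basal expression: cost is defined for Z >= z_basal.")
  if (params$form == "saturating") {
    if (any(Z >= params$m_sat))
      abort("`Z` >= m_sat: the saturating cost diverges.")
    params$eta0 * (Z - z_basal) / (1 - Z / params$m_sat)
  } else {
    params$eta0 * (Z - z_basal)
  }
}

#' Growth-rate benefit of Pgal metabolism
#'
#' `B(Z, P) = delta * Z^z_exponent * P^hill_p / (k_pgal^hill_p + P^hill_p)`:
#' zero without enzyme or substrate, saturating in P.
#'
#' @param Z Expression fraction(s) (>= 0).
#' @param P Pgal concentration(s), uM (>= 0).
#' @param params A [lac_benefit_params()] or [lac_growth_params()] object.
#' @return Growth-rate increment(s), doublings/hr.
#' @export
expression_benefit <- function(Z, P, params) {
  bp <- if (inherits(params, "lac_growth_params")) params$benefit else params
  if (!inherits(bp, "lac_benefit_params"))
    abort("`params` must carry benefit parameters.")
  if (any(Z < 0) || any(P < 0)) abort("`Z` and `P` must be nonnegative.")
  n <- max(length(Z), length(P))
  Z <- rep_len(Z, n); P <- rep_len(P, n)
  fp <- ifelse(P == 0, 0, 1 / (1 + (bp$k_pgal / P)^bp$hill_p))
  bp$delta * Z^bp$z_exponent * fp
}

#' Growth rate under decoupled induction and metabolism
#'
#' Composes [induction_response()], [expression_cost()] and
#' [expression_benefit()]:
#' `g(I, P) = g0 - eta(Z_reg(I, P)) + B(Z_reg(I, P), P)`.
#' `growth_rate(0, 0, params)` equals `g0` exactly (basal-cost absorption).
#'
#' @inheritParams induction_response
#' @param params A [lac_growth_params()] object.
#' @return Growth rate(s), doublings/hr.
#' @examples
#' growth_rate(0, 0, lac_default_params())     # basal rate, 1.09 dbl/hr
#' growth_rate(220, 0, lac_default_params())   # ~0.89: full-induction cost
#' @export
growth_rate <- function(I, P, params) {
  params <- as_growth_params(params)
  Z <- induction_response(I, P, params)
  params$g0 - expression_cost(Z, params) + expression_benefit(Z, P, params)
}

# Hill saturation in P, shared internally
.pgal_saturation <- function(P, bp) {
  ifelse(P <= 0, 0, 1 / (1 + (bp$k_pgal / P)^bp$hill_p))
}

# marginal cost eta'(Z); marginal benefit dB/dZ = a*delta*Z^(a-1)*f(P)
.marginal_cost <- function(Z, cp, zb) {
  if (cp$form == "saturating")
    cp$eta0 * (1 - zb / cp$m_sat) / (1 - Z / cp$m_sat)^2
  else rep_len(cp$eta0, length(Z))
}

#' Optimal expression level for a given Pgal concentration
#'
#' The expression level `Z_opt(P)` maximizing benefit minus cost,
#' `B(Z, P) - eta(Z)`, over `Z` in `[z_basal, z_max]`. For `z_exponent <= 1`
#' (concave benefit in Z) the interior optimum solves the marginal condition
#' `dB/dZ = deta/dZ`, inverted in closed form up to a monotone 1-D root;
#' otherwise a dense-grid search is used.
#'
#' @param P Pgal concentration(s), uM.
#' @param params A [lac_growth_params()] object.
#' @return Optimal expression fraction(s) in `[z_basal, z_max]`.
#' @export
optimal_expression <- function(P, params) {
  params <- as_growth_params(params)
  if (any(P < 0)) abort("`P` must be nonnegative.")
  vapply(P, .zopt_one, numeric(1), params = params)
}

.zopt_one <- function(P, params) {
  ip <- params$induction; cp <- params$cost; bp <- params$benefit
  zb <- params$z_cost_ref %||% ip$z_basal
  zm <- ip$z_max; a <- bp$z_exponent
  if (P <= 0 || bp$delta == 0) return(zb)
  fp <- .pgal_saturation(P, bp)
  if (cp$eta0 == 0) return(zm)  # pure-benefit limit
  if (a <= 1) {
    # marginal benefit at the boundaries vs marginal cost
    mb <- function(Z) a * bp$delta * Z^(a - 1) * fp   # decreasing for a < 1
    net_slope <- function(Z) mb(Z) - .marginal_cost(Z, cp, zb)
    lo <- max(zb, 1e-12)
    if (net_slope(lo) <= 0) return(zb)
    if (net_slope(zm) >= 0) return(zm)
    uniroot(net_slope, c(lo, zm), tol = 1e-12)$root
  } else {
    # benefit convex in Z: objective may be multimodal; grid + polish
    zg <- seq(zb, zm, length.out = 512)
    obj <- expression_benefit(zg, P, bp) - expression_cost(zg, cp, z_basal = zb)
    i <- which.max(obj)
    lo <- zg[max(1, i - 1)]; hi <- zg[min(length(zg), i + 1)]
    if (lo == hi) return(zg[i])
    o <- optimize(function(Z) expression_benefit(Z, P, bp) -
                    expression_cost(Z, cp, z_basal = zb),
                  c(lo, hi), maximum = TRUE, tol = 1e-10)
    cand <- c(o$maximum, zb, zm)
    vals <- expression_benefit(cand, P, bp) -
      expression_cost(cand, cp, z_basal = zb)
    cand[which.max(vals)]
  }
}

#' Optimal inducer concentration for a given Pgal concentration
#'
#' The IPTG concentration maximizing `growth_rate(I, P)`, found by 1-D
#' optimization on log(I) with an explicit check of I = 0. When the optimum is
#' not interior (the argmax exceeds `i_max` with less than 0.1% further
#' improvement available), `Inf` is returned as the "saturating" marker.
#'
#' @param P Pgal concentration(s), uM.
#' @param params A [lac_growth_params()] object.
#' @param i_max Largest IPTG concentration regarded as experimentally
#'   accessible (uM); beyond it the optimum is declared saturating.
#' @return Optimizing IPTG concentration(s), uM; `Inf` marks a saturating
#'   optimum.
#' @examples
#' optimal_inducer(100, lac_default_params())  # ~5 uM
#' optimal_inducer(240, lac_default_params())  # ~30 uM
#' @export
optimal_inducer <- function(P, params, i_max = 220) {
  params <- as_growth_params(params)
  if (any(P < 0)) abort("`P` must be nonnegative.")
  vapply(P, .iopt_one, numeric(1), params = params, i_max = i_max)
}

.iopt_one <- function(P, params, i_max) {
  g <- function(I) growth_rate(I, P, params)
  o <- optimize(function(u) g(10^u), c(-3, log10(i_max)),
                maximum = TRUE, tol = 1e-8)
  i_star <- 10^o$maximum
  g_star <- o$objective
  g0v <- g(0)
  if (g0v >= g_star) return(0)
  # near the top of the search range: saturating unless meaningfully
  # improvable beyond i_max
  if (o$maximum > log10(i_max) - 1e-4) {
    g_top <- g(i_max)
    g_far <- g(i_max * 1e4)
    if ((g_far - g_top) / abs(g_top) < 1e-3) return(Inf)
    o2 <- optimize(function(u) g(10^u),
                   c(log10(i_max), log10(i_max) + 6),
                   maximum = TRUE, tol = 1e-8)
    # still railing at the extended boundary: monotone approach to saturation
    if (o2$maximum > log10(i_max) + 6 - 1e-3) return(Inf)
    return(10^o2$maximum)
  }
  i_star
}

#' Pgal concentration at which benefit balances cost
#'
#' Solves `B(Z_reg(I, P), P) = eta(Z_reg(I, P))` for `P` at fixed inducer
#' level `I`, by bracketing root-finding. Anti-induction makes the expression
#' level itself P-dependent, so the full composed model is used. At the
#' balance point `growth_rate(I, P) = g0`.
#'
#' @param I IPTG concentration, uM, such that expression is above basal
#'   (otherwise there is no cost to offset).
#' @param params A [lac_growth_params()] object.
#' @param p_max Upper end of the root search, uM.
#' @return Balance Pgal concentration, uM.
#' @examples
#' balance_concentration(220, lac_default_params())  # ~120 uM
#' @export
balance_concentration <- function(I, params, p_max = 1e6) {
  params <- as_growth_params(params)
  if (length(I) != 1 || I < 0) abort("`I` must be a single nonnegative value.")
  h <- function(P) growth_rate(I, P, params) - params$g0
  cost0 <- expression_cost(induction_response(I, 0, params), params)
  if (cost0 <= 1e-12)
    abort("Zero-cost condition: `I` yields basal expression only, nothing to balance.")
  # bracket the first upward crossing of g = g0
  grid <- 10^seq(-2, log10(p_max), length.out = 400)
  hv <- vapply(grid, h, numeric(1))
  idx <- which(hv[-1] > 0 & hv[-length(hv)] <= 0)
  if (!length(idx)) {
    if (all(hv <= 0))
      abort("No root: expression cost exceeds the maximal attainable benefit.")
    abort("No bracketable cost-benefit crossing found below `p_max`.")
  }
  uniroot(h, c(grid[idx[1]], grid[idx[1] + 1]), tol = 1e-9)$root
}

#' Optimality curve Z_opt(P) with optimal inducer levels
#'
#' Tabulates the optimal expression level and the optimal inducer
#' concentration over a grid of Pgal concentrations, and locates the
#' inflection of `Z_opt(P)` (the P maximizing `dZ_opt/dP`) on a dense
#' monotone-spline interpolant of the tabulated curve.
#'
#' @param p_grid Strictly increasing Pgal concentrations (uM), at least 10
#'   points spanning the sigmoidal rise of `Z_opt`.
#' @param params A [lac_growth_params()] object.
#' @return A tibble of class `lac_optimality_curve` with columns `pgal`,
#'   `z_opt`, `i_opt` (uM, `Inf` marking saturating optima), and attributes
#'   `inflection_p` (uM) and `params`.
#' @seealso [lac_inflection()] to read the inflection point.
#' @export
optimality_curve <- function(p_grid, params) {
  params <- as_growth_params(params)
  if (length(p_grid) < 10) abort("`p_grid` needs at least 10 points.")
  if (any(diff(p_grid) <= 0)) abort("`p_grid` must be strictly increasing.")
  if (any(p_grid < 0)) abort("`p_grid` must be nonnegative.")
  z <- optimal_expression(p_grid, params)
  i <- optimal_inducer(p_grid, params)
  infl <- .inflection_from_table(p_grid, z)
  structure(
    tibble(pgal = p_grid, z_opt = z, i_opt = i),
    inflection_p = infl, params = params,
    class = c("lac_optimality_curve", class(tibble())))
}

.inflection_from_table <- function(p, z, n_dense = 4000) {
  # monotone spline; guard tiny numerical non-monotonicity
  z <- cummax(z)
  sf <- splinefun(p, z, method = "hyman")
  pd <- seq(min(p), max(p), length.out = n_dense)
  dz <- sf(pd, deriv = 1)
  i <- which.max(dz)
  span <- max(p) - min(p)
  if (pd[i] <= min(p) + 0.02 * span || pd[i] >= max(p) - 0.02 * span)
    abort(paste0("Inflection of Z_opt(P) not bracketed by the grid ",
                 "(steepest point at the grid edge); widen or refine `p_grid`."))
  o <- optimize(function(x) sf(x, deriv = 1),
                c(pd[max(1, i - 2)], pd[min(n_dense, i + 2)]),
                maximum = TRUE, tol = 1e-8)
  o$maximum
}

#' Inflection point of an optimality curve
#'
#' @param curve A `lac_optimality_curve` from [optimality_curve()].
#' @return Pgal concentration (uM) of the steepest rise of `Z_opt(P)`.
#' @export
lac_inflection <- function(curve) {
  v <- attr(curve, "inflection_p")
  if (is.null(v)) abort("`curve` has no inflection attribute; is it a `lac_optimality_curve`?")
  v
}
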