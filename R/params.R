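#' Induction (regulatory response) parameters
#'
#' Parameterizes the regulatory response `Z_reg(I, P)` of the lac operon: a
#' Hill function of the gratuitous inducer IPTG whose half-maximal point is
#' shifted to higher IPTG by competitive binding of the carbon source Pgal to
#' the repressor's inducer site (anti-induction),
#' `K_eff = k_half * (1 + P / k_anti)`.
#'
#' Expression is dimensionless, normalized so that the wild-type fully induced
#' level is 1.
#'
#' @param z_basal Basal (fully repressed) expression fraction.
#' @param z_max Fully induced expression fraction (wild type: 1).
#' @param k_half IPTG concentration (uM) at half-maximal induction when P = 0.
#' @param hill_n Hill coefficient of induction (> 0).
#' @param k_anti Pgal concentration scale (uM) of competitive anti-induction.
#' @return An object of class `lac_induction_params`.
#' @examples
#' lac_induction_params(z_basal = 0.005, k_half = 12, hill_n = 1.6)
#' @export
lac_induction_params <- function(z_basal = 0.005, z_max = 1, k_half = 12,
                                 hill_n = 1.6, k_anti = 1000) {
  p <- list(z_basal = z_basal, z_max = z_max, k_half = k_half,
            hill_n = hill_n, k_anti = k_anti)
  validate_induction_params(p)
  structure(p, class = "lac_induction_params")
}

validate_induction_params <- function(p) {
  stopifnot(is.numeric(p$z_basal), is.numeric(p$z_max))
  if (!(p$z_basal >= 0 && p$z_basal < p$z_max))
    abort("`z_basal` must satisfy 0 <= z_basal < z_max.")
  if (!(p$z_max <= 1.2))
    abort("`z_max` must not exceed 1.2 (expression is normalized to wild type).")
  if (!(p$k_half > 0)) abort("`k_half` must be positive.")
  if (!(p$hill_n > 0)) abort("`hill_n` must be positive.")
  if (!(p$k_anti > 0)) abort("`k_anti` must be positive.")
  invisible(p)
}

#' Expression cost parameters
#'
#' The growth-rate cost of producing the lac operon proteins at expression
#' level `Z`. The default saturating form,
#' `eta(Z) = eta0 * (Z - z_basal) / (1 - Z / m_sat)`,
#' diverges as `Z` approaches `m_sat` (the expression level at which protein
#' burden stalls growth); the linear form `eta0 * (Z - z_basal)` is kept for
#' sensitivity analyses. Cost is measured relative to basal expression, so
#' `eta(z_basal) = 0` by construction.
#'
#' @param eta0 Cost scale (doublings/hr per unit expression).
#' @param m_sat Expression fraction at which the saturating cost diverges;
#'   must exceed `z_max` of the accompanying induction parameters.
#' @param form `"saturating"` (default) or `"linear"`.
#' @return An object of class `lac_cost_params`.
#' @export
lac_cost_params <- function(eta0 = 0.134, m_sat = 3,
                            form = c("saturating", "linear")) {
  form <- arg_match(form)
  p <- list(eta0 = eta0, m_sat = m_sat, form = form)
  validate_cost_params(p)
  structure(p, class = "lac_cost_params")
}

validate_cost_params <- function(p) {
  if (!(is.numeric(p$eta0) && p$eta0 >= 0)) abort("`eta0` must be >= 0.")
  if (!p$form %in% c("saturating", "linear"))
    abort("`form` must be \"saturating\" or \"linear\".")
  if (p$form == "saturating" && !(p$m_sat > 0))
    abort("`m_sat` must be positive for the saturating cost form.")
  invisible(p)
}

#' Metabolic benefit parameters
#'
#' The growth-rate benefit of Pgal metabolism,
#' `B(Z, P) = delta * Z^z_exponent * P^hill_p / (k_pgal^hill_p + P^hill_p)`.
#' The benefit vanishes without enzyme (`Z = 0`) or substrate (`P = 0`) and
#' saturates at `delta * Z^z_exponent` for large `P`.
#'
#' @param delta Maximal benefit (doublings/hr) at full expression.
#' @param k_pgal Pgal half-saturation concentration (uM).
#' @param hill_p Hill exponent in Pgal (> 0).
#' @param z_exponent Exponent on expression. Values below 1 encode diminishing
#'   returns of enzyme level (e.g. uptake limitation).
#' @return An object of class `lac_benefit_params`.
#' @export
lac_benefit_params <- function(delta = 2.2, k_pgal = 380, hill_p = 2,
                               z_exponent = 1) {
  p <- list(delta = delta, k_pgal = k_pgal, hill_p = hill_p,
            z_exponent = z_exponent)
  validate_benefit_params(p)
  structure(p, class = "lac_benefit_params")
}

validate_benefit_params <- function(p) {
  if (!(is.numeric(p$delta) && p$delta >= 0)) abort("`delta` must be >= 0.")
  if (!(p$k_pgal > 0)) abort("`k_pgal` must be positive.")
  if (!(p$hill_p > 0)) abort("`hill_p` must be positive.")
  if (!(p$z_exponent > 0)) abort("`z_exponent` must be positive.")
  invisible(p)
}

#' Full growth-model parameter set
#'
#' Assembles the decoupled cost-benefit growth model
#' `g(I, P) = g0 - eta(Z_reg(I, P)) + B(Z_reg(I, P), P)`.
#' By the basal-cost absorption convention `g(0, 0) = g0` exactly: `g0` is the
#' measured growth rate in plain medium and already includes the (tiny) cost
#' of basal expression.
#'
#' @param g0 Basal growth rate (doublings/hr), set by nutrients other than
#'   Pgal.
#' @param induction A [lac_induction_params()] object.
#' @param cost A [lac_cost_params()] object.
#' @param benefit A [lac_benefit_params()] object.
#' @param z_cost_ref Expression level at which the cost is zero. `NULL`
#'   (default) uses the induction `z_basal`. Mutant genotypes built from a
#'   wild-type model keep the wild-type reference here, so that e.g. a
#'   constitutive lacI-null mutant still pays the full expression cost.
#' @return An object of class `lac_growth_params`.
#' @seealso [lac_default_params()] for the calibrated default set.
#' @export
lac_growth_params <- function(g0 = 1.09,
                              induction = lac_induction_params(),
                              cost = lac_cost_params(),
                              benefit = lac_benefit_params(),
                              z_cost_ref = NULL) {
  if (!inherits(induction, "lac_induction_params"))
    induction <- do.call(lac_induction_params, as.list(induction))
  if (!inherits(cost, "lac_cost_params"))
    cost <- do.call(lac_cost_params, as.list(cost))
  if (!inherits(benefit, "lac_benefit_params"))
    benefit <- do.call(lac_benefit_params, as.list(benefit))
  if (!(is.numeric(g0) && g0 > 0)) abort("`g0` must be positive.")
  if (cost$form == "saturating" && !(cost$m_sat > induction$z_max))
    abort("`m_sat` must exceed `z_max` for the saturating cost form.")
  if (!is.null(z_cost_ref) &&
      !(z_cost_ref >= 0 && z_cost_ref <= induction$z_max))
    abort("`z_cost_ref` must lie in [0, z_max].")
  structure(list(g0 = g0, induction = induction, cost = cost,
                 benefit = benefit, z_cost_ref = z_cost_ref),
            class = "lac_growth_params")
}

#' @export
print.lac_growth_params <- function(x, ...) {
  cat("<lac_growth_params>\n")
  cat(sprintf("  g0        %.4f dbl/hr\n", x$g0))
  cat(sprintf("  induction z_basal=%.4g z_max=%.3g k_half=%.3g uM hill_n=%.3g k_anti=%.3g uM\n",
              x$induction$z_basal, x$induction$z_max, x$induction$k_half,
              x$induction$hill_n, x$induction$k_anti))
  cat(sprintf("  cost      eta0=%.4g m_sat=%.3g form=%s\n",
              x$cost$eta0, x$cost$m_sat, x$cost$form))
  cat(sprintf("  benefit   delta=%.4g k_pgal=%.3g uM hill_p=%.3g z_exponent=%.3g\n",
              x$benefit$delta, x$benefit$k_pgal, x$benefit$hill_p,
              x$benefit$z_exponent))
  invisible(x)
}

# flat named vector <-> nested params, used by the fitter and calibration
PARAM_FIELDS <- c("g0", "z_basal", "z_max", "k_half", "hill_n", "k_anti",
                  "eta0", "m_sat", "delta", "k_pgal", "hill_p", "z_exponent")

params_to_vec <- function(params) {
  c(g0 = params$g0,
    z_basal = params$induction$z_basal, z_max = params$induction$z_max,
    k_half = params$induction$k_half, hill_n = params$induction$hill_n,
    k_anti = params$induction$k_anti,
    eta0 = params$cost$eta0, m_sat = params$cost$m_sat,
    delta = params$benefit$delta, k_pgal = params$benefit$k_pgal,
    hill_p = params$benefit$hill_p, z_exponent = params$benefit$z_exponent)
}

vec_to_params <- function(v, form = "saturating") {
  lac_growth_params(
    g0 = v[["g0"]],
    induction = lac_induction_params(z_basal = v[["z_basal"]],
                                     z_max = v[["z_max"]],
                                     k_half = v[["k_half"]],
                                     hill_n = v[["hill_n"]],
                                     k_anti = v[["k_anti"]]),
    cost = lac_cost_params(eta0 = v[["eta0"]], m_sat = v[["m_sat"]],
                           form = form),
    benefit = lac_benefit_params(delta = v[["delta"]], k_pgal = v[["k_pgal"]],
                                 hill_p = v[["hill_p"]],
                                 z_exponent = v[["z_exponent"]]))
}

#' Calibrated default growth-model parameters
#'
#' Returns the frozen parameter set obtained by [calibrate_ground_truth()],
#' shipped with the package in `extdata/ground_truth.json`. It reproduces the
#' anchor values of [lac_anchors()]: basal growth 1.09 doublings/hr, a
#' full-induction cost of 0.2 doublings/hr, cost-benefit balance at 120 uM
#' Pgal under 220 uM IPTG, optimal IPTG near 5 and 30 uM at 100 and 240 uM
#' Pgal, an optimal-expression inflection near 150 uM Pgal, and a maximal net
#' Pgal benefit of 1.6 doublings/hr.
#'
#' @return A [lac_growth_params()] object.
#' @export
lac_default_params <- function() {
  if (is.null(the$default_params)) {
    path <- system.file("extdata", "ground_truth.json", package = "lacoptim",
                        mustWork = TRUE)
    the$default_params <- read_ground_truth(path)$model
  }
  the$default_params
}

#' Default measurement noise (coefficient of variation)
#'
#' The pooled relative error of plate-reader growth-rate measurements used by
#' the synthetic-data generators: 4.3%.
#'
#' @return A scalar fraction.
#' @export
lac_default_noise_cv <- function() 0.043
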