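test_that("induction response has the right limits and half-point", {
  p <- toy_params()
  ip <- p$induction
  expect_equal(induction_response(0, 0, p), ip$z_basal)
  expect_equal(induction_response(1e6, 0, p), 1, tolerance = 1e-3)
  # half-saturation at K_eff = k_half * (1 + P/k_anti), by construction
  for (P in c(0, 100, 500)) {
    k_eff <- ip$k_half * (1 + P / ip$k_anti)
    z <- induction_response(k_eff, P, p)
    expect_equal(z, ip$z_basal + (ip$z_max - ip$z_basal) / 2)
  }
  expect_error(induction_response(-1, 0, p), "nonnegative")
  expect_error(induction_response(1, -1, p), "nonnegative")
})

test_that("induction is monotone in I and anti-monotone in P", {
  for (i in 1:10) {
    p <- random_params(i)
    I <- sort(runif(20, 0, 300))
    z <- induction_response(I, 50, p)
    expect_true(all(diff(z) >= 0))
    P <- sort(runif(20, 0, 2000))
    z2 <- induction_response(30, P, p)
    expect_true(all(diff(z2) <= 0))
  }
})

test_that("expression cost is zero at basal, increasing, and guarded", {
  p <- toy_params()
  zb <- p$induction$z_basal
  expect_equal(expression_cost(zb, p), 0)
  expect_lt(expression_cost(0.8, p), expression_cost(0.9, p))
  expect_error(expression_cost(p$cost$m_sat, p), "diverges")
  expect_error(expression_cost(zb - 0.001, p), "basal")
  lin <- lac_cost_params(eta0 = 0.1, form = "linear")
  expect_equal(expression_cost(0.5, lin), 0.05)
})

test_that("full-induction cost of the calibrated model is ~0.2 dbl/hr", {
  expect_equal(expression_cost(1, lac_default_params()), 0.2,
               tolerance = 0.02)
})

test_that("benefit vanishes without enzyme or substrate and saturates", {
  p <- toy_params()
  expect_equal(expression_benefit(1, 0, p), 0)
  expect_equal(expression_benefit(0, 500, p), 0)
  expect_equal(expression_benefit(1, 1e9, p), p$benefit$delta,
               tolerance = 1e-6)
  expect_error(expression_benefit(-0.1, 10, p), "nonnegative")
})

test_that("growth rate composes the pieces and honors the basal convention", {
  d <- lac_default_params()
  expect_identical(growth_rate(0, 0, d), d$g0)
  expect_equal(growth_rate(220, 0, d), 0.89, tolerance = 0.01)
  # at the balance concentration benefit offsets cost exactly
  expect_equal(growth_rate(220, 120, d), d$g0, tolerance = 1e-3)
  # cost-only regime: growth never exceeds g0 without Pgal
  I <- c(0, 1, 5, 20, 100, 500)
  expect_true(all(growth_rate(I, 0, d) <= d$g0 + 1e-12))
})

test_that("optimal expression matches a brute-force grid argmax", {
  for (i in 1:100) {
    p <- random_params(i)
    P <- withr::with_seed(2000 + i, runif(1, 0, 600))
    step <- (p$induction$z_max - p$induction$z_basal) / 1e4
    expect_lte(abs(optimal_expression(P, p) - zopt_bruteforce(P, p)),
               step * 1.01)
  }
})

test_that("optimal expression limits: no substrate, no cost, saturation", {
  p <- toy_params()
  expect_equal(optimal_expression(0, p), p$induction$z_basal)
  p_free <- toy_params()
  p_free$cost$eta0 <- 0
  for (P in c(1, 50, 400)) expect_equal(optimal_expression(P, p_free), 1)
  # P -> infinity limit of the marginal condition (z_exponent = 1):
  # Z = m_sat (1 - sqrt(eta0 (1 - zb/m_sat) / delta)), clipped
  zb <- p$induction$z_basal; m <- p$cost$m_sat
  z_inf <- m * (1 - sqrt(p$cost$eta0 * (1 - zb / m) / p$benefit$delta))
  z_inf <- min(max(z_inf, zb), p$induction$z_max)
  expect_equal(optimal_expression(1e9, p), z_inf, tolerance = 1e-6)
})

test_that("optimal inducer reproduces the observed optima and edge cases", {
  d <- lac_default_params()
  expect_identical(optimal_inducer(0, d), 0)
  i100 <- optimal_inducer(100, d)
  i240 <- optimal_inducer(240, d)
  expect_gt(i100, 5 / 1.5); expect_lt(i100, 5 * 1.5)
  expect_gt(i240, 30 / 1.5); expect_lt(i240, 30 * 1.5)
  # high Pgal: optimum saturates beyond the accessible range
  expect_identical(optimal_inducer(500, d), Inf)
})

test_that("balance concentration solves B = eta and round-trips to g0", {
  d <- lac_default_params()
  bal <- balance_concentration(220, d)
  expect_equal(bal, 120, tolerance = 0.15 * 120 / 120)
  expect_lt(abs(growth_rate(220, bal, d) - d$g0), 1e-6)
  # a second inducer level round-trips too
  bal2 <- balance_concentration(50, d)
  expect_lt(abs(growth_rate(50, bal2, d) - d$g0), 1e-6)
  expect_error(balance_concentration(0, d), "Zero-cost")
  # cost above the benefit ceiling: no root
  p_bad <- toy_params()
  p_bad$cost$eta0 <- 10
  expect_error(balance_concentration(220, p_bad), "No root")
})

test_that("optimality curve is monotone with a bracketed inflection", {
  d <- lac_default_params()
  oc <- optimality_curve(seq(1, 500, length.out = 60), d)
  expect_true(all(diff(oc$z_opt) >= -1e-9))
  infl <- lac_inflection(oc)
  expect_equal(infl, 150, tolerance = 0.2)
  # two-method agreement: dense numerical differentiation of the closed-form
  # Z_opt(P) versus the monotone-spline estimate
  pd <- seq(1, 500, length.out = 2500)
  zd <- optimal_expression(pd, d)
  dz <- diff(zd) / diff(pd)
  infl_direct <- pd[which.max(dz)]
  expect_equal(infl, infl_direct, tolerance = 0.05)
  # grid that misses the rise cannot bracket the inflection
  expect_error(optimality_curve(seq(350, 500, length.out = 12), d),
               "not bracketed")
  expect_error(optimality_curve(c(1, 2), d), "at least 10")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(lac_induction_params(z_basal = 0.5, z_max = 0.4), "z_basal")
  expect_error(lac_induction_params(k_half = -1), "k_half")
  expect_error(lac_benefit_params(delta = -1), "delta")
  expect_error(lac_growth_params(g0 = -1), "g0")
  expect_error(
    lac_growth_params(cost = lac_cost_params(m_sat = 0.9)), "m_sat")
})
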