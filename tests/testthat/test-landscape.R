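test_that("fitting a noise-free grid recovers the generating parameters", {
  truth <- default_truth()
  grid <- generate_growth_grid(truth, replicates = 1, seed = 1, noise_cv = 0)
  fit <- fit_growth_model(grid, init = truth$model, n_starts = 4)
  expect_true(fit$converged)
  rel <- abs(params_to_vec(fit$params) / params_to_vec(truth$model) - 1)
  expect_true(all(rel < 0.01))
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("a noisy replicated grid recovers the basal rate within a few percent", {
  truth <- default_truth()
  grid <- generate_growth_grid(truth, replicates = 3, seed = 11)
  fit <- fit_growth_model(grid, seed = 11)
  expect_true(fit$converged)
  expect_equal(fit$params$g0, 1.09, tolerance = 0.03)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "half_width") %in% names(td)))
  expect_equal(glance(fit)$n_conditions, 42)
})

test_that("with everything but g0 frozen, a flat grid fit is the weighted mean", {
  flat <- lac_growth_params(
    g0 = 1, induction = toy_params()$induction,
    cost = lac_cost_params(eta0 = 0, m_sat = 3),
    benefit = lac_benefit_params(delta = 0, k_pgal = 200))
  grid <- generate_growth_grid(flat, iptg_levels = c(0, 5, 50),
                               pgal_levels = c(0, 100, 300),
                               replicates = 3, seed = 2, noise_cv = 0.04)
  fit <- fit_growth_model(grid, init = flat,
                          frozen = setdiff(lacoptim:::PARAM_FIELDS, "g0"),
                          n_starts = 2)
  means <- lacoptim:::grid_condition_means(grid)
  w <- 1 / lacoptim:::condition_sigma(means)^2
  expect_equal(fit$params$g0, sum(w * means$mean_growth) / sum(w),
               tolerance = 1e-6)
})

test_that("parameter error shrinks with more replicates", {
  truth <- default_truth()
  err <- function(reps, seed) {
    grid <- generate_growth_grid(truth, replicates = reps, seed = seed)
    # a non-convergence flag (flat likelihood valley at few replicates) is
    # fine here; the test is about shrinkage of the parameter error
    fit <- suppressWarnings(
      fit_growth_model(grid, init = truth$model, n_starts = 4, seed = seed))
    v <- params_to_vec(fit$params); v0 <- params_to_vec(truth$model)
    mean(abs(v[c("g0", "eta0", "delta")] / v0[c("g0", "eta0", "delta")] - 1))
  }
  e3 <- mean(c(err(3, 21), err(3, 22)))
  e30 <- mean(c(err(30, 21), err(30, 22)))
  expect_lt(e30, e3)
})

test_that("degenerate grids and unknown frozen names are rejected", {
  truth <- default_truth()
  grid <- generate_growth_grid(truth, iptg_levels = c(0, 220),
                               pgal_levels = c(0, 100, 300), seed = 1)
  expect_error(fit_growth_model(grid), "Degenerate")
  good <- generate_growth_grid(truth, seed = 1)
  expect_error(fit_growth_model(good, frozen = "nope"), "Unknown parameter")
})

test_that("empirical optima pick the measured argmax, ties toward lower IPTG", {
  truth <- default_truth()
  grid <- generate_growth_grid(truth, replicates = 1, seed = 1, noise_cv = 0)
  opt <- empirical_optima(grid)
  expect_equal(opt$iptg_opt[opt$pgal == 0], 0)       # decreasing row
  expect_equal(opt$iptg_opt[opt$pgal == 100], 5)     # observed optimum
  expect_equal(opt$iptg_opt[opt$pgal == 240], 30)
  # permutation invariance
  shuf <- grid[withr::with_seed(4, sample(nrow(grid))), ]
  expect_equal(empirical_optima(shuf), opt)
  # exact tie breaks toward lower IPTG
  tie <- tibble::tibble(iptg = rep(c(0, 10, 50), 2),
                        pgal = rep(c(0, 100), each = 3),
                        replicate = 1, growth = c(1, 1, 0.9, 1, 1.2, 1.2))
  opt_tie <- empirical_optima(tie)
  expect_equal(opt_tie$iptg_opt, c(0, 10))
  # sparse rows are skipped with a warning
  sparse <- dplyr::bind_rows(tie, tibble::tibble(iptg = 0, pgal = 999,
                                                 replicate = 1, growth = 1))
  expect_warning(empirical_optima(sparse), "Skipping")
})

test_that("interpolated landscape is exact at nodes as smoothing vanishes", {
  truth <- default_truth()
  grid <- generate_growth_grid(truth, replicates = 1, seed = 1, noise_cv = 0)
  surf <- interpolate_landscape(grid, smoothing = 0)
  expect_lt(max(abs(surf(grid$iptg, grid$pgal) - grid$growth)), 1e-6)
  # per-row argmax over the measured levels agrees with empirical optima
  opt <- empirical_optima(grid)
  for (P in unique(grid$pgal)) {
    iv <- sort(unique(grid$iptg))
    expect_equal(iv[which.max(surf(iv, P))], opt$iptg_opt[opt$pgal == P])
  }
  # monotone in P below the anti-induction scale at high induction
  pv <- seq(0, 500, by = 25)
  expect_true(all(diff(surf(rep(220, length(pv)), pv)) > 0))
})

test_that("GCV smoothing reproduces replicate means within twice the noise", {
  truth <- default_truth()
  grid <- generate_growth_grid(truth, replicates = 3, seed = 31)
  surf <- interpolate_landscape(grid)
  means <- lacoptim:::grid_condition_means(grid)
  resid <- surf(means$iptg, means$pgal) - means$mean_growth
  expect_true(all(abs(resid) < 2 * truth$noise_cv * means$mean_growth))
  expect_error(surf(1e4, 1e4), "convex hull")
  expect_silent(interpolate_landscape(grid, allow_extrapolation = TRUE)(1e4, 1e4))
})

test_that("tradeoff cross dominates all constant-expression points", {
  d <- lac_default_params()
  tc <- tradeoff_curve(d, 39, 500, i_list = c(0, 2, 5, 15, 30, 50, 100, 220))
  expect_true(all(tc$points$g_low <= tc$cross[["g_low"]] + 1e-12))
  expect_true(all(tc$points$g_high <= tc$cross[["g_high"]] + 1e-12))
  # low expression is optimal in the low-Pgal environment
  expect_equal(tc$points$iptg[which.max(tc$points$g_low)], 0)
  # duplicate I entries do not change the curve
  tc2 <- tradeoff_curve(d, 39, 500,
                        i_list = c(0, 0, 2, 5, 15, 30, 50, 100, 220, 220))
  expect_equal(tc2$points, tc$points)
  # the Pareto front is monotone decreasing
  pts <- tc$points
  nd <- vapply(seq_len(nrow(pts)), function(i) {
    !any(pts$g_low >= pts$g_low[i] & pts$g_high >= pts$g_high[i] &
           (pts$g_low > pts$g_low[i] | pts$g_high > pts$g_high[i]))
  }, logical(1))
  front <- pts[nd, ] |> dplyr::arrange(g_low)
  expect_true(all(diff(front$g_high) <= 1e-12))
})

test_that("regulation advantage is nonnegative and vanishes at the cross", {
  d <- lac_default_params()
  tc <- tradeoff_curve(d, 39, 500)
  for (w in seq(0, 1, by = 0.1))
    expect_gte(regulation_advantage(tc, w), 0)
  # a single point sitting at the high-environment optimum gives zero
  # advantage when all weight is on that environment
  i_star <- optimal_inducer(240, d)
  tc_pt <- tradeoff_curve(d, 39, 240, i_list = i_star)
  expect_lt(regulation_advantage(tc_pt, weight_low = 0), 1e-6)
  # the advantage of regulating is limited: well under 10% of the cross
  adv <- regulation_advantage(tc, 0.5)
  cross_avg <- mean(tc$cross)
  expect_lt(adv, 0.1 * cross_avg)
  expect_error(regulation_advantage(tc, 1.5), "weight_low")
})

test_that("concavity index is positive for the calibrated front, zero when degenerate", {
  d <- lac_default_params()
  tc <- tradeoff_curve(d, 39, 500)
  expect_gt(concavity_index(tc), 0)
  # two points only
  tc2 <- tradeoff_curve(d, 39, 500, i_list = c(0, 220))
  expect_warning(ci2 <- concavity_index(tc2), "Fewer than 3")
  expect_equal(ci2, 0)
  # collinear points lie on the chord
  lin <- structure(list(
    points = tibble::tibble(iptg = 1:3, g_low = c(1, 0.75, 0.5),
                            g_high = c(0.5, 0.75, 1)),
    cross = c(g_low = 1, g_high = 1), p_low = 39, p_high = 500),
    class = "lac_tradeoff")
  expect_equal(concavity_index(lin), 0)
})
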