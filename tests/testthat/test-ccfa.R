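ps_small <- polychoric_summary(tiny_data(200, seed = 51))

test_that("constraint patterns have the expected degrees of freedom", {
  # 2 groups x (J(C-1) thresholds + J(J-1)/2 correlations) = 40 statistics
  f_conf <- fit_mgccfa(ps_small, "configural")
  f_met <- fit_mgccfa(ps_small, "metric")
  f_scal <- fit_mgccfa(ps_small, "scalar")
  f_null <- fit_mgccfa(ps_small, "null")
  expect_equal(f_met$df - f_conf$df, 4)            # J - 1 loadings freed
  expect_equal(f_scal$df - f_met$df, 8)            # (J-1)(C-1) thresholds
  expect_equal(f_scal$df - f_conf$df, (5 - 1) + (5 - 1) * (3 - 1))
  expect_equal(f_null$df, 5 * (5 - 1))             # all correlations
  # step-down releases: loading df 1, thresholds df C-1
  f_l <- fit_mgccfa(ps_small, "stepdown", item = 3, which = "loading")
  f_t <- fit_mgccfa(ps_small, "stepdown", item = 3, which = "thresholds")
  expect_equal(f_scal$df - f_l$df, 1)
  expect_equal(f_scal$df - f_t$df, 2)
  expect_error(fit_mgccfa(ps_small, "stepdown", item = 1,
                          which = "loading"), "anchor")
  # C = 5: thresholds release frees 4 parameters
  ps5 <- polychoric_summary(tiny_data(200, C = 5, seed = 52))
  expect_equal(fit_mgccfa(ps5, "scalar")$df -
                 fit_mgccfa(ps5, "stepdown", item = 2,
                            which = "thresholds")$df, 4)
})

test_that("DWLS discrepancy is monotone over nested constraint patterns", {
  for (seed in c(61, 62)) {
    ps <- polychoric_summary(tiny_data(300, seed = seed))
    u <- vapply(c("configural", "metric", "scalar"),
                function(p) fit_mgccfa(ps, p)$chisq_unscaled, numeric(1))
    expect_true(all(diff(u) >= -1e-6))
  }
})

test_that("chi-square difference arithmetic and behavior", {
  mk <- function(chisq, df) structure(
    list(chisq = chisq, chisq_unscaled = chisq, df = df, UG = NULL),
    class = "mi_ccfa_fit")
  d <- chisq_diff(mk(55, 44), mk(50, 40), method = "naive")
  expect_equal(d$statistic, 5)
  expect_equal(d$df, 4)
  expect_equal(d$p, pchisq(5, 4, lower.tail = FALSE))
  expect_equal(round(d$p, 4), 0.2873)
  # identical statistics: T = 0, p = 1
  d0 <- chisq_diff(mk(50, 44), mk(50, 40), method = "naive")
  expect_equal(d0$statistic, 0)
  expect_equal(d0$p, 1)
  expect_error(chisq_diff(mk(50, 40), mk(55, 44)), "nested")
  # scaled-shifted difference on real nested fits is nonnegative with the
  # right df
  f_met <- fit_mgccfa(ps_small, "metric")
  f_conf <- fit_mgccfa(ps_small, "configural")
  d <- chisq_diff(f_met, f_conf)
  expect_gte(d$statistic, 0)
  expect_equal(d$df, 4)
  expect_true(d$p >= 0 && d$p <= 1)
})

test_that("RMSEA and CFI arithmetic oracles", {
  expect_equal(rmsea(40, 40, 500), 0)
  expect_equal(rmsea(60, 40, 500, n_groups = 2),
               sqrt(2) * sqrt(20 / (40 * 499)), tolerance = 1e-12)
  expect_equal(rmsea(60, 40, 500, n_groups = 1) /
                 rmsea(60, 40, 500, n_groups = 2), 1 / sqrt(2),
               tolerance = 1e-12)
  # printed variant differs by construction
  expect_equal(rmsea(60, 40, 500, form = "printed"),
               sqrt(2) * sqrt(60 / 40 - 1 / 499), tolerance = 1e-12)
  expect_error(rmsea(10, 0, 100), "df")
  expect_equal(cfi(30, 20, 300, 40), 1 - 10 / 260, tolerance = 1e-12)
  expect_equal(cfi(20, 20, 300, 40), 1)
  expect_equal(cfi(300, 40, 300, 40), 0)
  expect_equal(cfi(15, 20, 300, 40), 1)   # floored numerator
})

test_that("large-sample estimates recover the generating parameters", {
  pop <- base_population(5, 3)
  d <- simulate_responses(pop, 50000, seed = 71)
  f <- fit_mgccfa(polychoric_summary(d), "scalar")
  expect_true(f$converged)
  lam_true <- pop$reference$loadings / sqrt(pop$reference$unique_variances)
  tau_true <- pop$reference$thresholds /
    sqrt(pop$reference$unique_variances)
  expect_lt(max(abs(f$estimates$r$loadings - lam_true)), 0.02)
  expect_lt(max(abs(f$estimates$r$thresholds - tau_true)), 0.02)
  expect_lt(abs(f$estimates$f$factor_mean), 0.03)
  expect_lt(abs(f$estimates$f$factor_variance - 1), 0.05)
  # anchor parameters identical across groups by construction
  expect_equal(f$estimates$r$loadings[1], f$estimates$f$loadings[1])
  expect_equal(f$estimates$r$thresholds[1, ], f$estimates$f$thresholds[1, ])
})

test_that("analytic Jacobian of implied statistics matches numerical", {
  model <- ordmi:::ccfa_model(5, 3, "stepdown", item = 4,
                              which = "thresholds")
  set.seed(8)
  th <- rnorm(model$npar, 0, 0.4)
  th[seq_len(model$n_lam)] <- abs(th[seq_len(model$n_lam)]) + 0.3
  mf <- ordmi:::ccfa_implied_fun(model)
  jf <- ordmi:::ccfa_jacobian_fun(model)
  expect_equal(jf(th), numDeriv::jacobian(mf, th), tolerance = 1e-6)
})

test_that("invariance sequence and step-down fit together coherently", {
  sq <- invariance_sequence(ps_small)
  expect_true(sq$converged)
  expect_equal(sq$tests$parameter, c("loadings", "thresholds"))
  expect_equal(sq$tests$df, c(4, 8))
  expect_true(all(sq$tests$p >= 0 & sq$tests$p <= 1))
  # null model fits thresholds exactly: its residuals live on correlations
  expect_gt(sq$fits$null$chisq, sq$fits$scalar$chisq)
  # structural zero: model-implied correlation is zero in the null pattern
  sd <- stepdown_item_test(ps_small, 2, "thresholds",
                           scalar_fit = sq$fits$scalar,
                           null_fit = sq$fits$null)
  expect_equal(sd$df, 2)
  expect_true(sd$converged)
  # releasing one item's constraints can only reduce the discrepancy
  expect_lte(sd$fit$chisq_unscaled, sq$fits$scalar$chisq_unscaled + 1e-6)
  # refitting the scalar model from the step-down solution's neighborhood
  # returns the same optimum (round trip)
  refit <- fit_mgccfa(ps_small, "scalar",
                      start = sq$fits$scalar$theta + 0.05)
  expect_equal(refit$chisq_unscaled, sq$fits$scalar$chisq_unscaled,
               tolerance = 1e-4)
})
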