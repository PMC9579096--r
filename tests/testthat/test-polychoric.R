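test_that("univariate thresholds are inverse-normal cumulative proportions", {
  expect_equal(univariate_thresholds(c(100, 100, 100)),
               qnorm(c(1, 2) / 3), tolerance = 1e-12)
  expect_equal(univariate_thresholds(c(50, 50)), 0)
  expect_equal(univariate_thresholds(c(200, 100, 100, 200)),
               qnorm(c(1 / 3, 1 / 2, 2 / 3)))
  expect_error(univariate_thresholds(c(0, 100, 50)),
               class = "ordmi_degenerate")
  expect_error(univariate_thresholds(c(100, 0, 50)),
               class = "ordmi_degenerate")
  expect_error(univariate_thresholds(c(0, 0, 0)), "invalid")
})

test_that("tetrachoric closed form: symmetric table at zero thresholds", {
  # P(both low) = 1/4 + asin(rho)/(2*pi); proportions ((1/3,1/6),(1/6,1/3))
  # invert for rho = sin(2*pi*(1/3 - 1/4)) = 0.5
  tb <- matrix(c(1 / 3, 1 / 6, 1 / 6, 1 / 3) * 6000, 2)
  expect_equal(polychoric_rho(tb, 0, 0), 0.5, tolerance = 1e-6)
  # independence: rho approximately zero
  ind <- outer(c(30, 50, 20), c(25, 40, 35)) # counts proportional to margins
  tx <- univariate_thresholds(rowSums(ind))
  ty <- univariate_thresholds(colSums(ind))
  expect_lt(abs(polychoric_rho(ind, tx, ty)), 1e-6)
})

test_that("two-step estimate equals brute-force grid-search ML", {
  tabs <- list(
    matrix(c(40, 10, 0, 10, 30, 10, 0, 10, 40), 3, byrow = TRUE),
    matrix(c(5, 20, 40, 20, 30, 20, 45, 15, 5), 3, byrow = TRUE),
    matrix(c(80, 20, 5, 25, 40, 30, 10, 30, 60), 3, byrow = TRUE)
  )
  for (tb in tabs) {
    tx <- univariate_thresholds(rowSums(tb))
    ty <- univariate_thresholds(colSums(tb))
    expect_equal(polychoric_rho(tb, tx, ty), grid_rho(tb, tx, ty),
                 tolerance = 1e-3)
  }
})

test_that("polychoric correlations are consistent for factor-model data", {
  pop <- base_population(5, 3)
  d <- simulate_responses(pop, 1e5, seed = 21)
  ps <- polychoric_summary(d, acov = FALSE)
  truth <- pop_polychoric(pop)
  expect_lt(max(abs(ps$groups$r$rho - truth)), 0.01)
  expect_lt(max(abs(ps$groups$f$rho - truth)), 0.01)
  # estimated thresholds near the population values (total variance is 1)
  expect_lt(max(abs(ps$groups$r$tau - pop$reference$thresholds)), 0.02)
})

test_that("asymptotic covariance is symmetric, PSD-diagonal and scales as 1/N", {
  d <- tiny_data(400, seed = 31)
  ps <- polychoric_summary(d)
  A <- ps$groups$r$acov
  expect_equal(A, t(A))
  expect_true(all(diag(A) > 0))
  expect_equal(nrow(A), 5 * 2 + 10)
  # doubling the data with identical proportions halves the covariance
  X <- d$responses[d$group == "r", ]
  a1 <- polychoric_acov(X, ps$groups$r$tau, ps$groups$r$rho, C = 3)
  a2 <- polychoric_acov(rbind(X, X), ps$groups$r$tau, ps$groups$r$rho, C = 3)
  expect_equal(a1, 2 * a2, tolerance = 1e-10)
})

test_that("influence-function covariance matches a bootstrap oracle", {
  pop <- base_population(5, 3)
  pop$reference$loadings <- pop$focal$loadings <- c(.5, .7, .6, 0, 0)[1:3]
  pop$reference$unique_variances <- pop$focal$unique_variances <-
    1 - pop$reference$loadings^2
  pop$reference$thresholds <- pop$focal$thresholds <-
    pop$reference$thresholds[1:3, ]
  d <- simulate_responses(pop, 600, seed = 41)
  X <- d$responses[d$group == "r", ]
  ps_stat <- function(X) {
    tau <- sapply(1:3, function(j)
      univariate_thresholds(tabulate(X[, j] + 1L, 3)))
    rho <- sapply(list(c(1, 2), c(1, 3), c(2, 3)), function(pr) {
      tb <- table(factor(X[, pr[1]], levels = 0:2),
                  factor(X[, pr[2]], levels = 0:2))
      polychoric_rho(tb, tau[, pr[1]], tau[, pr[2]])
    })
    c(as.vector(tau), rho)
  }
  est <- ps_stat(X)
  tau_hat <- matrix(est[1:6], 3, 2, byrow = TRUE)
  rho_hat <- diag(3)
  rho_hat[lower.tri(rho_hat)] <- rho_hat[upper.tri(rho_hat)] <- est[7:9]
  # both layouts are thresholds item-major, then pairs (2,1), (3,1), (3,2)
  A <- polychoric_acov(X, tau_hat, rho_hat, C = 3)
  set.seed(99)
  B <- 600
  boot <- t(replicate(B, ps_stat(X[sample(nrow(X), replace = TRUE), ])))
  vb <- apply(boot, 2, var)
  expect_true(all(abs(diag(A) - vb) / vb < 0.15))
})
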