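test_that("base population reproduces the fixed parameter table", {
  pop <- base_population(5, 3)
  expect_equal(pop$reference$loadings[2], 0.7)
  expect_equal(pop$reference$unique_variances[2], 0.51)
  expect_equal(pop$reference$thresholds[2, ], c(0.12, 0.88))
  expect_equal(base_population(5, 5)$reference$thresholds[1, ],
               c(-0.84, -0.25, 0.25, 0.84))
  # standardized generation: loading^2 + unique variance = 1 for every item
  for (C in c(3, 5)) {
    p <- base_population(5, C)$reference
    expect_equal(p$loadings^2 + p$unique_variances, rep(1, 5))
    expect_true(all(diff(t(p$thresholds)) > 0))
  }
  # long scale repeats the block five times
  p25 <- base_population(25, 3)$reference
  p5 <- base_population(5, 3)$reference
  expect_equal(p25$loadings[6:10], p5$loadings)
  expect_equal(p25$thresholds[11:15, ], p5$thresholds)
  # both groups identical at baseline
  pop <- base_population(25, 5)
  expect_identical(pop$reference, pop$focal)
  expect_error(base_population(7, 3), "n_items")
  expect_error(base_population(5, 4), "n_categories")
})

test_that("anchor thresholds are the quantiles of the standardized item", {
  th5 <- derive_anchor_thresholds(5, loading = 0.5, n_draws = 1e6, seed = 3)
  expect_equal(th5, qnorm(c(.2, .4, .6, .8)), tolerance = 0.01)
  th3 <- derive_anchor_thresholds(3, loading = 0.5, n_draws = 1e6, seed = 4)
  expect_equal(th3, qnorm(c(1, 2) / 3), tolerance = 0.01)
  # the +0.50 shifted quintiles match the table values of items 2 and 5
  expect_equal(round(qnorm(c(.2, .4, .6, .8)) + 0.5, 2),
               c(-0.34, 0.25, 0.75, 1.34), tolerance = 0.011)
  expect_error(derive_anchor_thresholds(4), "3 or 5")
})

test_that("loading and threshold non-invariance is injected as specified", {
  pop <- base_population(5, 3)
  # large aligned loading change on 20% of items: item 2 only, .7 -> .9
  p <- apply_dif(pop, pct_loading = 20, magnitude = "large")
  expect_equal(p$focal$loadings[2], 0.9)
  expect_equal(p$focal$loadings[2]^2, 0.81)
  expect_equal(p$focal$loadings[-2], pop$reference$loadings[-2])
  expect_identical(p$reference, pop$reference)
  # small aligned: .7 -> .8, explained variance .64
  p <- apply_dif(pop, pct_loading = 20, magnitude = "small")
  expect_equal(p$focal$loadings[2], 0.8)
  # 40% misaligned: items 2 (+) and 3 (-); mean loading conserved
  p <- apply_dif(pop, pct_loading = 40, alignment = "misaligned",
                 magnitude = "large")
  expect_equal(p$focal$loadings[2:3], c(0.9, 0.4))
  expect_equal(mean(p$focal$loadings[2:3]),
               mean(pop$reference$loadings[2:3]))
  # 40% aligned raises the mean of affected loadings by exactly d
  p <- apply_dif(pop, pct_loading = 40, magnitude = "small")
  expect_equal(mean(p$focal$loadings[2:3]) -
                 mean(pop$reference$loadings[2:3]), 0.1)
  # thresholds: whole vector shifted, same item-selection logic
  p <- apply_dif(pop, pct_threshold = 40, alignment = "misaligned",
                 magnitude = "large")
  expect_equal(p$focal$thresholds[2, ], pop$reference$thresholds[2, ] + 0.5)
  expect_equal(p$focal$thresholds[3, ], pop$reference$thresholds[3, ] - 0.5)
  expect_equal(p$focal$thresholds[c(1, 4, 5), ],
               pop$reference$thresholds[c(1, 4, 5), ])
  # anchor item is never selected
  for (pct in c(20, 40)) {
    p <- apply_dif(pop, pct_loading = pct, pct_threshold = pct)
    expect_equal(p$focal$loadings[1], p$reference$loadings[1])
    expect_equal(p$focal$thresholds[1, ], p$reference$thresholds[1, ])
  }
  # 25 items, 40%: items 2..11, first five up, last five down
  p <- apply_dif(base_population(25, 3), pct_threshold = 40,
                 alignment = "misaligned", magnitude = "small")
  moved <- which(rowSums(p$focal$thresholds != p$reference$thresholds) > 0)
  expect_equal(moved, 2:11)
  expect_equal(p$focal$thresholds[7, ] - p$reference$thresholds[7, ],
               rep(-0.25, 2))
  # identity and error cases
  expect_identical(apply_dif(pop, 0, 0)$focal, pop$focal)
  expect_error(apply_dif(pop, pct_loading = 20, alignment = "misaligned"),
               "misaligned")
  bad <- pop
  bad$focal$loadings[2] <- bad$reference$loadings[2] <- 0.95
  expect_error(apply_dif(bad, pct_loading = 20, magnitude = "large"),
               "outside")
})

test_that("response generation matches the discretized factor model", {
  pop <- base_population(5, 3)
  d <- simulate_responses(pop, 300, seed = 11)
  expect_s3_class(d, "mi_data")
  expect_equal(dim(d$responses), c(600, 5))
  expect_true(all(d$responses %in% 0:2))
  expect_equal(as.integer(table(d$group)), c(300, 300))
  # determinism
  d2 <- simulate_responses(pop, 300, seed = 11)
  expect_identical(d$responses, d2$responses)
  # category marginals: for a standardized item the proportions converge to
  # the normal-CDF increments at the thresholds (item 1, N = 1e5)
  big <- simulate_responses(pop, 1e5, seed = 12)
  tau <- pop$reference$thresholds[1, ]
  expected <- diff(c(0, pnorm(tau), 1))
  observed <- tabulate(big$responses[, 1] + 1L, 3) / 2e5
  se <- sqrt(expected * (1 - expected) / 2e5)
  expect_true(all(abs(observed - expected) < 3 * se))
  # zero loadings: items are independent of the factor and of each other
  pop0 <- pop
  pop0$reference$loadings <- pop0$focal$loadings <- rep(0, 5)
  d0 <- simulate_responses(pop0, 20000, seed = 13)
  cors <- cor(d0$responses)
  expect_lt(max(abs(cors[lower.tri(cors)])), 0.03)
})

test_that("dataset and population serialization round-trips", {
  pop <- apply_dif(base_population(5, 3), pct_loading = 20)
  d <- simulate_responses(pop, 40, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_mi_data(d, f)
  d2 <- read_mi_data(f)
  expect_identical(d$responses, d2$responses)
  expect_identical(d$group, d2$group)
  expect_equal(d2$n_categories, 3L)
  header <- readLines(f, n = 1)
  expect_equal(header, "group,item1,item2,item3,item4,item5")
  fy <- tempfile(fileext = ".yaml")
  write_mi_population(pop, fy)
  pop2 <- read_mi_population(fy)
  expect_equal(pop2$focal$loadings, pop$focal$loadings)
  expect_equal(pop2$reference$thresholds, pop$reference$thresholds)
  unlink(c(f, fy))
})
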