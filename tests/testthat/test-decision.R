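test_that("scale-level combined criterion follows the stated rule", {
  crit <- criterion_config()
  mkseq <- function(p, dr, dc) structure(
    list(tests = data.frame(parameter = "loadings", statistic = 1, df = 4,
                            p = p, delta_rmsea = dr, delta_cfi = dc)),
    class = "mi_ccfa_sequence")
  fl <- function(p, dr, dc) {
    d <- decide_scale_ccfa(mkseq(p, dr, dc), crit)
    stats::setNames(d$flagged, d$method)
  }
  f <- fl(0.01, 0.02, 0)       # significant test + RMSEA change
  expect_true(f["chisq"]); expect_true(f["drmsea"])
  expect_false(f["dcfi"]); expect_true(f["combined"])
  f <- fl(0.01, 0.002, -0.002) # significant test, no index change
  expect_true(f["chisq"]); expect_false(f["combined"])
  f <- fl(0.5, 0.02, 0)        # index change without significance
  expect_true(f["drmsea"]); expect_false(f["combined"])
  # the "or" reading flags whenever any criterion fires
  crit_or <- criterion_config(combined_rule = "or")
  d <- decide_scale_ccfa(mkseq(0.5, 0.02, 0), crit_or)
  expect_true(d$flagged[d$method == "combined"])
})

test_that("item-to-scale aggregation uses a Bonferroni threshold", {
  crit <- criterion_config()
  expect_equal(crit$alpha / 25, 0.002)
  expect_false(decide_scale_irt(c(.03, .2, .5, .9, .04), crit))
  expect_true(decide_scale_irt(c(rep(.5, 24), .0005), crit))
  expect_true(decide_scale_irt(c(.009, .5, .5, .5, .5), crit))
  # the R2-style extra requirement gates aggregation item-wise
  expect_false(decide_scale_irt(c(.001, .5, .5, .5, .5), crit,
                                extra_ok = c(FALSE, TRUE, TRUE, TRUE, TRUE)))
  expect_true(decide_scale_irt(c(.001, .5, .5, .5, .5), crit,
                               extra_ok = c(TRUE, FALSE, FALSE, FALSE,
                                            FALSE)))
  expect_error(decide_scale_irt(numeric(0), crit), "no item")
})

test_that("condition runner tallies rates over converged replications", {
  cnd <- condition_spec(5, 3, 150, n_reps = 3, seed = 7)
  r <- run_condition(cnd, engines = c("ccfa_scale", "lor"),
                     parameters = "loadings")
  expect_s3_class(r, "mi_condition_result")
  expect_true(all(r$rates$value >= 0 & r$rates$value <= 1))
  # invariance condition: no true positives exist, only FPR rows
  expect_true(all(r$rates$rate_type == "fpr"))
  expect_equal(r$cr$converged, c(3, 3))
  expect_true(all(r$cr$cr > 0 & r$cr$cr <= 1))
  # determinism: same seed, same rates
  r2 <- run_condition(cnd, engines = c("ccfa_scale", "lor"),
                      parameters = "loadings")
  expect_identical(r$rates, r2$rates)
})

test_that("non-invariance conditions yield TPR rows for affected items", {
  cnd <- condition_spec(5, 3, 200, pct_threshold = 40,
                        alignment = "misaligned", magnitude = "large",
                        n_reps = 3, seed = 17)
  r <- run_condition(cnd, engines = "ccfa_item", parameters = "thresholds")
  tpr <- r$rates[r$rates$rate_type == "tpr", ]
  fpr <- r$rates[r$rates$rate_type == "fpr", ]
  expect_true(nrow(tpr) > 0 && nrow(fpr) > 0)
  # 2 of 4 tested items truly shifted, pooled over 3 reps
  expect_equal(unique(tpr$n_units), 6)
  expect_equal(unique(fpr$n_units), 6)
})

test_that("summaries reshape to one condition row per table and round-trip", {
  cnd <- condition_spec(5, 3, 150, n_reps = 2, seed = 27)
  r <- run_condition(cnd, engines = "lor", parameters = "loadings")
  dir <- tempfile()
  sm <- summarize_results(list(r), dir = dir)
  expect_true(file.exists(file.path(dir, "fpr_scale_loadings.csv")))
  expect_true(file.exists(file.path(dir, "convergence.csv")))
  tb <- sm$tables$fpr_scale_loadings
  expect_equal(nrow(tb), 1)
  expect_true(all(c("lor.lrt", "lor.r2") %in% names(tb)))
  # same master seed reproduces byte-identical rate tables
  r2 <- run_condition(cnd, engines = "lor", parameters = "loadings")
  dir2 <- tempfile()
  summarize_results(list(r2), dir = dir2)
  expect_identical(readLines(file.path(dir, "fpr_scale_loadings.csv")),
                   readLines(file.path(dir2, "fpr_scale_loadings.csv")))
  unlink(c(dir, dir2), recursive = TRUE)
})

test_that("study configuration files drive the runner", {
  cfg <- list(
    n_reps = 2, seed = 5,
    engines = "lor", parameters = "loadings",
    conditions = list(list(n_items = 5, n_categories = 3,
                           n_per_group = 150))
  )
  f <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(cfg), f)
  res <- run_study(f)
  expect_length(res, 1)
  expect_s3_class(res[[1]], "mi_condition_result")
  unlink(f)
})
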