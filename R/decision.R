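#' Decision-criterion configuration
#'
#' Collects the cutoffs and multiplicity policies used to turn test output
#' into invariance decisions: significance level for all chi-square-type
#' tests, the fit-index change cutoffs (`delta-RMSEA > .01`,
#' `delta-CFI < -.01`), the logistic-regression effect-size cutoff
#' (`delta-R2 > .02`), and whether the scale-level combined criterion
#' requires the chi-square test AND at least one index
#' (`combined_rule = "and"`, the reported criterion) or ANY criterion
#' (`"or"`).
#'
#' @param alpha Significance level.
#' @param delta_rmsea_cut,delta_cfi_cut,delta_r2_cut Index cutoffs.
#' @param combined_rule `"and"` or `"or"`.
#' @return List of class `mi_criteria`.
#' @export
criterion_config <- function(alpha = 0.05, delta_rmsea_cut = 0.01,
                             delta_cfi_cut = -0.01, delta_r2_cut = 0.02,
                             combined_rule = c("and", "or")) {
  stopifnot(alpha > 0, alpha < 1, delta_rmsea_cut > 0, delta_cfi_cut < 0,
            delta_r2_cut > 0)
  structure(
    list(alpha = alpha, delta_rmsea_cut = delta_rmsea_cut,
         delta_cfi_cut = delta_cfi_cut, delta_r2_cut = delta_r2_cut,
         combined_rule = match.arg(combined_rule)),
    class = "mi_criteria"
  )
}

ccfa_flags <- function(p, delta_rmsea, delta_cfi, criteria, alpha) {
  chisq <- p < alpha
  drmsea <- delta_rmsea > criteria$delta_rmsea_cut
  dcfi <- delta_cfi < criteria$delta_cfi_cut
  combined <- if (criteria$combined_rule == "and")
    chisq && (drmsea || dcfi) else (chisq || drmsea || dcfi)
  c(chisq = chisq, drmsea = drmsea, dcfi = dcfi, combined = combined)
}

#' Scale-level decisions from an invariance sequence
#'
#' Applies the four criteria (chi-square difference test, delta-RMSEA,
#' delta-CFI, and the combined rule) to the loadings (metric vs configural)
#' and thresholds (scalar vs metric) comparisons.
#'
#' @param sequence An `mi_ccfa_sequence` from [invariance_sequence()].
#' @param criteria An `mi_criteria` object.
#' @return Data frame with `parameter`, `method`, `flagged`.
#' @export
decide_scale_ccfa <- function(sequence, criteria = criterion_config()) {
  tests <- sequence$tests
  out <- lapply(seq_len(nrow(tests)), function(r) {
    fl <- ccfa_flags(tests$p[r], tests$delta_rmsea[r], tests$delta_cfi[r],
                     criteria, criteria$alpha)
    data.frame(parameter = tests$parameter[r], method = names(fl),
               flagged = as.logical(fl), row.names = NULL)
  })
  do.call(rbind, out)
}

#' Scale-level decision from item-level p-values
#'
#' Flags the scale as non-invariant when at least one item test survives a
#' Bonferroni correction (`alpha / number of item tests`); for the
#' logistic-regression R2 criterion the per-item effect-size requirement
#' must additionally hold for the same item.
#'
#' @param item_pvalues One p-value per tested item.
#' @param criteria An `mi_criteria` object.
#' @param extra_ok Optional logical vector (e.g. `delta_r2 > cut`) combined
#'   with the per-item significance before aggregation.
#' @return Logical flag.
#' @export
decide_scale_irt <- function(item_pvalues, criteria = criterion_config(),
                             extra_ok = NULL) {
  if (length(item_pvalues) == 0) stop("no item p-values", call. = FALSE)
  thr <- criteria$alpha / length(item_pvalues)
  hit <- item_pvalues < thr
  if (!is.null(extra_ok)) hit <- hit & extra_ok
  any(hit)
}

#' Simulation condition specification
#'
#' One cell of the simulation design: scale length, number of categories,
#' group size, and the non-invariance pattern injected into the focal group.
#'
#' @param n_items 5 or 25.
#' @param n_categories 3 or 5.
#' @param n_per_group Persons per group.
#' @param pct_loading,pct_threshold Percentage of items with non-invariant
#'   loadings / thresholds (0, 20, 40).
#' @param alignment `"aligned"` or `"misaligned"` (misaligned only at 40%).
#' @param magnitude `"small"` or `"large"`.
#' @param n_reps Converged replications required.
#' @param seed Master seed of the condition.
#' @return List of class `mi_condition`.
#' @export
condition_spec <- function(n_items, n_categories, n_per_group,
                           pct_loading = 0, pct_threshold = 0,
                           alignment = "aligned", magnitude = "small",
                           n_reps = 500, seed = 1) {
  pop <- apply_dif(base_population(n_items, n_categories),
                   pct_loading, pct_threshold, alignment, magnitude)
  structure(
    list(n_items = n_items, n_categories = n_categories,
         n_per_group = n_per_group, pct_loading = pct_loading,
         pct_threshold = pct_threshold, alignment = alignment,
         magnitude = magnitude, n_reps = n_reps, seed = seed,
         population = pop),
    class = "mi_condition"
  )
}

# deterministic per-attempt seed stream (kept well below 2^31)
attempt_seed <- function(master, t) {
  (((master %% 1000003) + 13) * 2099 + t * 9973) %% 2147483629 + 1
}

# ---- per-attempt engine analyses -------------------------------------------

analyze_ccfa_scale <- function(ps, criteria) {
  sq <- invariance_sequence(ps)
  if (!sq$converged) return(NULL)
  decide_scale_ccfa(sq, criteria)
}

analyze_ccfa_item <- function(ps, criteria, parameters) {
  J <- ps$n_items
  items <- setdiff(seq_len(J), 1L)
  n_tests <- length(items)
  scalar_fit <- fit_mgccfa(ps, "scalar")
  if (!scalar_fit$converged) return(NULL)
  null_fit <- fit_mgccfa(ps, "null")
  out <- list()
  for (par in parameters) {
    wh <- if (par == "loadings") "loading" else "thresholds"
    for (it in items) {
      td <- stepdown_item_test(ps, it, wh, scalar_fit, null_fit)
      if (!td$converged) return(NULL)
      fl <- ccfa_flags(td$p, td$delta_rmsea, td$delta_cfi, criteria,
                       criteria$alpha / n_tests)
      out[[length(out) + 1L]] <-
        data.frame(item = it, parameter = par, method = names(fl),
                   flagged = as.logical(fl), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

analyze_irt <- function(data, criteria, parameters) {
  fc <- tryCatch(fit_mg_grm(data), ordmi_nonconvergence = function(e) NULL)
  if (is.null(fc) || !fc$converged) return(NULL)
  J <- ncol(data$responses)
  items <- setdiff(seq_len(J), 1L)
  rows <- list()
  for (par in parameters) {
    wh <- if (par == "loadings") "loading" else "thresholds"
    ps <- numeric(length(items))
    for (k in seq_along(items)) {
      lr <- tryCatch(grm_lrt(data, items[k], wh, constrained_fit = fc),
                     ordmi_nonconvergence = function(e) NULL)
      if (is.null(lr) || !lr$converged) return(NULL)
      ps[k] <- lr$p
    }
    rows[[length(rows) + 1L]] <- data.frame(
      level = "item", item = items, parameter = par, method = "lrt",
      flagged = ps < criteria$alpha, row.names = NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      level = "scale", item = NA_integer_, parameter = par, method = "lrt",
      flagged = decide_scale_irt(ps, criteria), row.names = NULL)
  }
  do.call(rbind, rows)
}

analyze_lor <- function(data, criteria, parameters, purify = TRUE) {
  res <- tryCatch({
    if (purify) {
      pr <- purified_scores(data, alpha = criteria$alpha)
      if (is.null(pr$table)) lor_dif(data, pr$scores, tests = "omnibus")
      else pr$table
    } else {
      lor_dif(data, pooled_scores(data), tests = "omnibus")
    }
  }, ordmi_nonconvergence = function(e) NULL,
  ordmi_degenerate = function(e) NULL)
  if (is.null(res)) return(NULL)
  r2ok <- res$delta_r2 > criteria$delta_r2_cut
  rows <- list()
  for (par in parameters) {
    for (m in c("lrt", "r2")) {
      item_fl <- if (m == "lrt") res$p_omnibus < criteria$alpha
      else res$p_omnibus < criteria$alpha & r2ok
      rows[[length(rows) + 1L]] <- data.frame(
        level = "item", item = res$item, parameter = par, method = m,
        flagged = item_fl, row.names = NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        level = "scale", item = NA_integer_, parameter = par, method = m,
        flagged = decide_scale_irt(
          res$p_omnibus, criteria,
          extra_ok = if (m == "r2") r2ok else NULL),
        row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Run one simulation condition
#'
#' Loops replications of one design cell: generates two-group data, runs the
#' requested engines, applies all decision criteria and tallies convergence,
#' false-positive and true-positive rates. Each engine consumes the shared
#' deterministic attempt stream independently: when an engine's analysis does
#' not converge on an attempt, that engine simply moves to the next attempt
#' (fresh data) until `n_reps` converged analyses are reached, so rates are
#' always computed over `n_reps` converged replications and
#' `CR = n_reps / attempts`.
#'
#' @param condition An `mi_condition` from [condition_spec()].
#' @param criteria An `mi_criteria` object.
#' @param engines Subset of `"ccfa_scale"`, `"ccfa_item"`, `"irt"`, `"lor"`.
#' @param parameters Subset of `"loadings"`, `"thresholds"`: which parameter
#'   types are tested.
#' @param purify Use purified latent scores in the logistic-regression
#'   engine (see [purified_scores()]); `FALSE` scores once from the pooled
#'   sample.
#' @param max_attempt_factor Abort when attempts exceed
#'   `max_attempt_factor * n_reps`.
#' @param progress Print a dot every 25 attempts.
#' @return Object of class `mi_condition_result`: `rates` (data frame with
#'   `engine`, `level`, `parameter`, `method`, `rate_type` (fpr/tpr),
#'   `value`, `n_units`), `cr` (per-engine convergence rates), `attempts`,
#'   and the condition.
#' @export
run_condition <- function(condition,
                          criteria = criterion_config(),
                          engines = c("ccfa_scale", "ccfa_item", "irt",
                                      "lor"),
                          parameters = c("loadings", "thresholds"),
                          purify = TRUE,
                          max_attempt_factor = 50,
                          progress = FALSE) {
  stopifnot(inherits(condition, "mi_condition"))
  engines <- match.arg(engines, several.ok = TRUE)
  parameters <- match.arg(parameters, several.ok = TRUE)
  pop <- condition$population
  J <- condition$n_items
  dif_load <- which(pop$reference$loadings != pop$focal$loadings)
  dif_thr <- which(rowSums(pop$reference$thresholds !=
                             pop$focal$thresholds) > 0)
  truth_items <- list(loadings = dif_load, thresholds = dif_thr)

  need <- stats::setNames(rep(condition$n_reps, length(engines)), engines)
  used <- stats::setNames(rep(0L, length(engines)), engines)
  tallies <- list()
  t <- 0L
  cap <- max_attempt_factor * condition$n_reps
  while (any(need > 0) && t < cap) {
    t <- t + 1L
    if (progress && t %% 25L == 0L) cat(".")
    data <- simulate_responses(pop, condition$n_per_group,
                               seed = attempt_seed(condition$seed, t))
    ps <- NULL
    need_ccfa <- any(need[names(need) %in% c("ccfa_scale", "ccfa_item")] > 0)
    if (need_ccfa) {
      ps <- tryCatch(polychoric_summary(data),
                     ordmi_nonconvergence = function(e) NULL)
    }
    for (eng in engines) {
      if (need[eng] == 0L) next
      used[eng] <- used[eng] + 1L
      res <- switch(eng,
        ccfa_scale = if (is.null(ps)) NULL
          else analyze_ccfa_scale(ps, criteria),
        ccfa_item = if (is.null(ps)) NULL
          else analyze_ccfa_item(ps, criteria, parameters),
        irt = analyze_irt(data, criteria, parameters),
        lor = analyze_lor(data, criteria, parameters, purify = purify)
      )
      if (is.null(res)) next
      need[eng] <- need[eng] - 1L
      if (eng == "ccfa_scale") {
        res <- data.frame(level = "scale", item = NA_integer_, res)
        res <- res[res$parameter %in% parameters, ]
      } else if (eng == "ccfa_item") {
        res <- data.frame(level = "item", res)
      }
      res$engine <- eng
      tallies[[length(tallies) + 1L]] <- res
    }
  }
  if (any(need > 0))
    stop(sprintf(
      "condition aborted: engines did not reach %d converged reps in %d attempts (%s)",
      condition$n_reps, t,
      paste(names(need)[need > 0], collapse = ", ")), call. = FALSE)

  all_flags <- do.call(rbind, tallies)
  rates <- list()
  for (eng in unique(all_flags$engine)) {
    fe <- all_flags[all_flags$engine == eng, ]
    for (lev in unique(fe$level)) {
      fl <- fe[fe$level == lev, ]
      for (par in unique(fl$parameter)) {
        fp <- fl[fl$parameter == par, ]
        for (m in unique(fp$method)) {
          fm <- fp[fp$method == m, ]
          if (lev == "scale") {
            truly_dif <- length(truth_items[[par]]) > 0
            rate_type <- if (truly_dif) "tpr" else "fpr"
            rates[[length(rates) + 1L]] <- data.frame(
              engine = eng, level = lev, parameter = par, method = m,
              rate_type = rate_type, value = mean(fm$flagged),
              n_units = nrow(fm))
          } else {
            dif <- fm$item %in% truth_items[[par]]
            for (rt in c("fpr", "tpr")) {
              sel <- if (rt == "fpr") !dif else dif
              if (!any(sel)) next
              rates[[length(rates) + 1L]] <- data.frame(
                engine = eng, level = lev, parameter = par, method = m,
                rate_type = rt, value = mean(fm$flagged[sel]),
                n_units = sum(sel))
            }
          }
        }
      }
    }
  }
  if (progress) cat("\n")
  structure(
    list(condition = condition, criteria = criteria,
         rates = do.call(rbind, rates),
         cr = data.frame(engine = engines,
                         converged = condition$n_reps,
                         attempts = as.integer(used[engines]),
                         cr = condition$n_reps / as.numeric(used[engines]),
                         row.names = NULL),
         attempts = t),
    class = "mi_condition_result"
  )
}

#' @export
print.mi_condition_result <- function(x, ...) {
  cn <- x$condition
  cat(sprintf(
    "Condition J=%d C=%d N=%d load%%=%d thr%%=%d %s/%s (%d reps)\n",
    cn$n_items, cn$n_categories, cn$n_per_group, cn$pct_loading,
    cn$pct_threshold, cn$alignment, cn$magnitude, cn$n_reps))
  cat("convergence:\n"); print(x$cr, digits = 3)
  cat("rates:\n"); print(x$rates, digits = 3)
  invisible(x)
}

#' Run a study described by a YAML configuration
#'
#' The configuration lists `conditions` (each a map of [condition_spec()]
#' arguments), optional `criteria` overrides, `engines`, `parameters`,
#' `n_reps` and `seed` defaults.
#'
#' @param config Path to a YAML file or an equivalent list.
#' @param progress Passed to [run_condition()].
#' @return List of `mi_condition_result`.
#' @export
run_study <- function(config, progress = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  crit <- do.call(criterion_config,
                  if (is.null(config$criteria)) list() else config$criteria)
  engines <- config$engines %||% c("ccfa_scale", "ccfa_item", "irt", "lor")
  parameters <- config$parameters %||% c("loadings", "thresholds")
  lapply(config$conditions, function(cnd) {
    cnd$n_reps <- cnd$n_reps %||% config$n_reps %||% 500
    cnd$seed <- cnd$seed %||% config$seed %||% 1
    run_condition(do.call(condition_spec, cnd), crit,
                  engines = engines, parameters = parameters,
                  progress = progress)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize condition results into report tables
#'
#' Collects a list of condition results into one long data frame and,
#' optionally, writes one CSV per (level, parameter, rate type) with
#' conditions as rows and engine/criterion columns, plus a YAML provenance
#' file (seeds, attempts, package version).
#'
#' @param results List of `mi_condition_result`.
#' @param dir Optional output directory.
#' @return Invisibly, a list with `long` (all rates), `cr` (all convergence
#'   rates) and `tables` (the wide tables).
#' @export
summarize_results <- function(results, dir = NULL) {
  lab <- function(cn) sprintf("J%d_C%d_N%d_L%d_T%d_%s_%s",
                              cn$n_items, cn$n_categories, cn$n_per_group,
                              cn$pct_loading, cn$pct_threshold,
                              cn$alignment, cn$magnitude)
  long <- do.call(rbind, lapply(results, function(r)
    data.frame(condition = lab(r$condition), r$rates)))
  cr <- do.call(rbind, lapply(results, function(r)
    data.frame(condition = lab(r$condition), r$cr)))
  long$column <- paste(long$engine, long$method, sep = ".")
  tables <- list()
  for (lev in unique(long$level)) for (par in unique(long$parameter))
    for (rt in unique(long$rate_type)) {
      sub <- long[long$level == lev & long$parameter == par &
                    long$rate_type == rt, ]
      if (nrow(sub) == 0) next
      wide <- stats::reshape(
        sub[, c("condition", "column", "value")],
        direction = "wide", idvar = "condition", timevar = "column")
      names(wide) <- sub("^value\\.", "", names(wide))
      tables[[paste(rt, lev, par, sep = "_")]] <- wide
    }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(cr, file.path(dir, "convergence.csv"),
                     row.names = FALSE)
    prov <- list(
      package = "ordmi",
      version = as.character(utils::packageVersion("ordmi")),
      date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
      conditions = lapply(results, function(r)
        r$condition[c("n_items", "n_categories", "n_per_group",
                      "pct_loading", "pct_threshold", "alignment",
                      "magnitude", "n_reps", "seed")])
    )
    writeLines(yaml::as.yaml(prov), file.path(dir, "provenance.yaml"))
  }
  invisible(list(long = long, cr = cr, tables = tables))
}
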