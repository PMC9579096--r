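#' One-shot pooled latent trait scores
#'
#' Fits a single-group graded response model to the pooled sample (groups
#' merged, standard-normal latent distribution) and returns the expected a
#' posteriori (EAP) score of every person. The scores are estimated once and
#' subsequently treated as observed covariates by the logistic-regression
#' DIF procedure; the uncertainty this ignores is precisely what makes the
#' unguarded likelihood-ratio criterion liberal on short scales.
#'
#' @param data An `mi_data` object.
#' @param ... Passed to [fit_mg_grm()].
#' @return Numeric vector of EAP scores (length = total N, in data order).
#' @export
pooled_scores <- function(data, ...) {
  fit <- fit_mg_grm(data, pooled = TRUE, ...)
  if (!fit$converged)
    stop(errorCondition("pooled scoring model did not converge",
                        class = "ordmi_nonconvergence"))
  fit$eap
}

# intercept-only cumulative-logit log-likelihood has the closed form
# sum n_c log(n_c / n)
loglik_intercept_only <- function(y, C) {
  cnt <- tabulate(y + 1L, nbins = C)
  cnt <- cnt[cnt > 0]
  sum(cnt * log(cnt / sum(cnt)))
}

#' Cumulative-logit model sequence for one item
#'
#' Fits the four nested proportional-odds models used for logistic-regression
#' DIF: intercepts only (Model 0), plus the latent score (Model 1), plus the
#' group main effect (Model 2), plus the score-by-group interaction
#' (Model 3). Slopes are shared across the C-1 cumulative splits; intercepts
#' are category-specific. Models 1-3 are fitted by maximum likelihood via
#' `MASS::polr`, cascading each fit's estimates into the next model's
#' starting values so the log-likelihoods are guaranteed non-decreasing.
#'
#' @param item_responses Integer vector in `0..C-1`.
#' @param scores Latent trait estimates, treated as observed.
#' @param groups Factor with two levels (reference first).
#' @param n_categories Number of categories C.
#' @return Object of class `mi_lor_models`: `loglik` (numeric vector, models
#'   0-3) and the three `polr` fits.
#' @export
fit_lor_sequence <- function(item_responses, scores, groups,
                             n_categories = max(item_responses) + 1L) {
  y <- factor(item_responses, levels = 0:(n_categories - 1L), ordered = TRUE)
  if (any(tabulate(item_responses + 1L, nbins = n_categories) == 0))
    stop(errorCondition("empty category in pooled item responses",
                        class = c("ordmi_degenerate",
                                  "ordmi_nonconvergence")))
  g <- as.numeric(groups == levels(groups)[2L])
  df <- data.frame(y = y, s = scores, g = g)
  ll0 <- loglik_intercept_only(item_responses, n_categories)
  fits <- vector("list", 3L)
  forms <- list(y ~ s, y ~ s + g, y ~ s + g + s:g)
  start <- NULL
  lls <- c(ll0, rep(NA_real_, 3L))
  for (m in 1:3) {
    nslope <- m
    st <- if (is.null(start)) NULL else c(start$coef, 0, start$zeta)
    fit <- tryCatch(
      suppressWarnings(
        if (is.null(st))
          MASS::polr(forms[[m]], data = df, method = "logistic")
        else
          MASS::polr(forms[[m]], data = df, method = "logistic", start = st)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(stats::logLik(fit)))
      stop(errorCondition(
        sprintf("cumulative-logit model %d did not converge", m),
        class = "ordmi_nonconvergence"))
    lls[m + 1L] <- as.numeric(stats::logLik(fit))
    fits[[m]] <- fit
    start <- list(coef = fit$coefficients, zeta = fit$zeta)
  }
  # guard against local optima breaking the nesting chain
  if (any(diff(lls) < -1e-6))
    stop(errorCondition("log-likelihood nesting violated",
                        class = "ordmi_nonconvergence"))
  structure(list(loglik = lls, fits = fits), class = "mi_lor_models")
}

#' Likelihood-ratio DIF statistics from a fitted model sequence
#'
#' `G2_omnibus = 2(l3 - l1)` (df 2), `G2_uniform = 2(l2 - l1)` (df 1),
#' `G2_nonuniform = 2(l3 - l2)` (df 1); the omnibus statistic equals the sum
#' of the other two by construction.
#'
#' @param model_set An `mi_lor_models` object.
#' @return Data frame with one row per test: `test`, `statistic`, `df`, `p`.
#' @export
g2_tests <- function(model_set) {
  ll <- model_set$loglik
  g2 <- c(omnibus = 2 * (ll[4] - ll[2]),
          uniform = 2 * (ll[3] - ll[2]),
          nonuniform = 2 * (ll[4] - ll[3]))
  if (any(g2 < -1e-6))
    stop("negative likelihood-ratio statistic: estimation inconsistency",
         call. = FALSE)
  g2 <- pmax(g2, 0)
  df <- c(2L, 1L, 1L)
  data.frame(test = names(g2), statistic = as.numeric(g2), df = df,
             p = pchisq(g2, df, lower.tail = FALSE), row.names = NULL)
}

#' McFadden pseudo-R-squared difference
#'
#' `R2_m = 1 - loglik_m / loglik_0`; returns the difference between the two
#' models of the requested comparison (omnibus: Model 3 vs Model 1).
#'
#' @param model_set An `mi_lor_models` object.
#' @param comparison `"omnibus"` (3 vs 1), `"uniform"` (2 vs 1) or
#'   `"nonuniform"` (3 vs 2).
#' @return The pseudo-R-squared difference.
#' @export
mcfadden_delta <- function(model_set,
                           comparison = c("omnibus", "uniform",
                                          "nonuniform")) {
  comparison <- match.arg(comparison)
  ll <- model_set$loglik
  if (ll[1] >= 0) stop("null log-likelihood must be negative", call. = FALSE)
  r2 <- 1 - ll / ll[1]
  switch(comparison,
         omnibus = r2[4] - r2[2],
         uniform = r2[3] - r2[2],
         nonuniform = r2[4] - r2[3])
}

# omnibus-only model pair (Models 1 and 3): enough for the flagging
# criteria and the purification loop
lor_omnibus <- function(item_responses, scores, groups, C) {
  y <- factor(item_responses, levels = 0:(C - 1L), ordered = TRUE)
  if (any(tabulate(item_responses + 1L, nbins = C) == 0))
    stop(errorCondition("empty category in pooled item responses",
                        class = c("ordmi_degenerate",
                                  "ordmi_nonconvergence")))
  g <- as.numeric(groups == levels(groups)[2L])
  df <- data.frame(y = y, s = scores, g = g)
  f1 <- tryCatch(suppressWarnings(
    MASS::polr(y ~ s, data = df, method = "logistic")),
    error = function(e) NULL)
  if (is.null(f1)) stop(errorCondition("cumulative-logit model 1 failed",
                                       class = "ordmi_nonconvergence"))
  st <- c(f1$coefficients, 0, 0, f1$zeta)
  f3 <- tryCatch(suppressWarnings(
    MASS::polr(y ~ s + g + s:g, data = df, method = "logistic",
               start = st)),
    error = function(e) NULL)
  if (is.null(f3)) stop(errorCondition("cumulative-logit model 3 failed",
                                       class = "ordmi_nonconvergence"))
  ll0 <- loglik_intercept_only(item_responses, C)
  ll1 <- as.numeric(stats::logLik(f1))
  ll3 <- as.numeric(stats::logLik(f3))
  g2 <- max(2 * (ll3 - ll1), 0)
  list(g2 = g2, p = pchisq(g2, 2, lower.tail = FALSE),
       delta_r2 = (1 - ll3 / ll0) - (1 - ll1 / ll0))
}

#' Purified latent trait scores
#'
#' Iterative score purification as performed by standard logistic-regression
#' DIF software: starting from one-shot pooled EAP scores, every item is
#' screened with the omnibus 2-df test; if any item is flagged, a
#' multiple-group graded response model is refitted with the flagged items'
#' parameters group-specific (the unflagged items act as the anchor) and the
#' EAP scores are recomputed from the group-specific parameters. The loop
#' stops when the flagged set is stable (or after `max_iter` iterations).
#' False flags make the recomputed scores group-dependent, which is the
#' mechanism that inflates subsequent DIF tests on short scales.
#'
#' @param data An `mi_data` object.
#' @param alpha Flagging level of the screening test.
#' @param max_iter Maximum purification iterations.
#' @param ... Passed to [fit_mg_grm()].
#' @return List with `scores`, `flagged` (final flagged item set),
#'   `iterations`, and `table` (per-item omnibus `g2`, `p` and `delta_r2`
#'   evaluated at the returned scores).
#' @export
purified_scores <- function(data, alpha = 0.05, max_iter = 10L, ...) {
  J <- ncol(data$responses)
  sc <- pooled_scores(data, ...)
  flagged <- integer(0)
  for (it in seq_len(max_iter)) {
    om <- lapply(seq_len(J), function(j)
      lor_omnibus(data$responses[, j], sc, data$group, data$n_categories))
    tab <- data.frame(item = seq_len(J),
                      g2_omnibus = vapply(om, `[[`, numeric(1), "g2"),
                      p_omnibus = vapply(om, `[[`, numeric(1), "p"),
                      delta_r2 = vapply(om, `[[`, numeric(1), "delta_r2"))
    new_flag <- which(tab$p_omnibus < alpha)
    done <- list(scores = sc, flagged = new_flag, iterations = it,
                 table = tab)
    if (length(new_flag) == 0L || setequal(new_flag, flagged))
      return(done)
    if (length(new_flag) >= J)   # nothing left to anchor on
      return(done)
    flagged <- new_flag
    # every unflagged item anchors the metric; flagged items are freed in
    # both parameters
    anch <- setdiff(seq_len(J), flagged)[1L]
    fit <- fit_mg_grm(data, freed = list(item = flagged, what = "both"),
                      anchor = anch, ...)
    if (!fit$converged)
      stop(errorCondition("purification calibration did not converge",
                          class = "ordmi_nonconvergence"))
    sc <- fit$eap
  }
  # iteration cap reached: the table no longer matches the final scores
  list(scores = sc, flagged = flagged, iterations = max_iter, table = NULL)
}

#' Logistic-regression DIF analysis of every item
#'
#' Computes pooled EAP scores once, then fits the Model 0-3 sequence for each
#' item and returns the omnibus, uniform and nonuniform likelihood-ratio
#' statistics together with the omnibus McFadden pseudo-R-squared difference.
#'
#' @param data An `mi_data` object.
#' @param scores Optional precomputed score vector (default: one-shot pooled
#'   EAP scores).
#' @param tests `"all"` fits Models 0-3 per item; `"omnibus"` skips Model 2
#'   (the uniform/nonuniform split), which the flagging criteria never use.
#' @return Data frame with one row per item: `item`, `g2_omnibus`,
#'   `p_omnibus`, `delta_r2`, and (with `tests = "all"`) `g2_uniform`,
#'   `p_uniform`, `g2_nonuniform`, `p_nonuniform`.
#' @export
lor_dif <- function(data, scores = NULL, tests = c("all", "omnibus")) {
  stopifnot(inherits(data, "mi_data"))
  tests <- match.arg(tests)
  if (is.null(scores)) scores <- pooled_scores(data)
  J <- ncol(data$responses)
  out <- lapply(seq_len(J), function(j) {
    if (tests == "omnibus") {
      om <- lor_omnibus(data$responses[, j], scores, data$group,
                        data$n_categories)
      return(data.frame(item = j, g2_omnibus = om$g2,
                        p_omnibus = om$p, delta_r2 = om$delta_r2))
    }
    ms <- fit_lor_sequence(data$responses[, j], scores, data$group,
                           data$n_categories)
    g2 <- g2_tests(ms)
    data.frame(item = j,
               g2_omnibus = g2$statistic[1], p_omnibus = g2$p[1],
               g2_uniform = g2$statistic[2], p_uniform = g2$p[2],
               g2_nonuniform = g2$statistic[3], p_nonuniform = g2$p[3],
               delta_r2 = mcfadden_delta(ms, "omnibus"))
  })
  do.call(rbind, out)
}

#' Flag an item under the logistic-regression criteria
#'
#' `criterion = "LRT"`: flag when the omnibus 2-df test is significant.
#' `criterion = "R2"`: additionally require the omnibus McFadden
#' `delta-R2 > r2_cut` (default .02).
#'
#' @param p_omnibus Omnibus test p-value.
#' @param delta_r2 Omnibus pseudo-R-squared difference.
#' @param criterion `"LRT"` or `"R2"`.
#' @param alpha Significance level.
#' @param r2_cut Effect-size cutoff.
#' @return Logical flag.
#' @export
lor_decide <- function(p_omnibus, delta_r2, criterion = c("LRT", "R2"),
                       alpha = 0.05, r2_cut = 0.02) {
  criterion <- match.arg(criterion)
  sig <- p_omnibus < alpha
  if (criterion == "LRT") sig else sig && delta_r2 > r2_cut
}
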