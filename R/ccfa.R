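#' @importFrom stats nlminb
NULL

# ordered-threshold reparameterization: tau <-> (tau1, log gaps)
tau_to_theta <- function(tau) c(tau[1], log(diff(tau)))
theta_to_tau <- function(th) cumsum(c(th[1], exp(th[-1])))

# Model descriptor for the multiple-group categorical factor model under the
# minimal anchor identification: unique variances fixed to 1 in both groups,
# reference factor N(0,1), focal factor mean/variance free, anchor item's
# loading and thresholds equal across groups in every pattern.
ccfa_model <- function(J, C, pattern, item = NULL, which = NULL,
                       anchor = 1L) {
  pattern <- match.arg(pattern, c("configural", "metric", "scalar",
                                  "stepdown", "null"))
  if (pattern == "stepdown") {
    which <- match.arg(which, c("loading", "thresholds"))
    if (is.null(item) || item == anchor || item < 1L || item > J)
      stop("step-down item must be a non-anchor item", call. = FALSE)
  }
  if (pattern == "null") {
    return(list(pattern = "null", J = J, C = C, anchor = anchor,
                npar = 2L * J * (C - 1L)))
  }
  lam_map <- rbind(seq_len(J), seq_len(J))
  tau_map <- rbind(seq_len(J), seq_len(J))
  if (pattern == "configural") {
    free_f <- setdiff(seq_len(J), anchor)
    lam_map[2, free_f] <- J + seq_along(free_f)
    tau_map[2, free_f] <- J + seq_along(free_f)
  } else if (pattern == "metric") {
    free_f <- setdiff(seq_len(J), anchor)
    tau_map[2, free_f] <- J + seq_along(free_f)
  } else if (pattern == "stepdown") {
    if (which == "loading") lam_map[2, item] <- J + 1L
    else tau_map[2, item] <- J + 1L
  }
  n_lam <- max(lam_map)
  n_tb <- max(tau_map)
  npar <- n_lam + n_tb * (C - 1L) + 2L
  list(pattern = pattern, J = J, C = C, anchor = anchor, item = item,
       which = which, lam_map = lam_map, tau_map = tau_map,
       n_lam = n_lam, n_tb = n_tb, npar = npar)
}

# row-wise (tau1, log-gaps) -> ordered thresholds for a block matrix
theta_to_tau_rows <- function(tb) {
  taus <- tb
  if (ncol(tb) > 1L) {
    for (cc in 2:ncol(tb))
      taus[, cc] <- taus[, cc - 1L] + exp(tb[, cc])
  }
  taus
}

# unpack theta into per-group parameters (theta scale: unique variances 1)
ccfa_pars <- function(model, theta) {
  J <- model$J; C <- model$C
  lam <- theta[seq_len(model$n_lam)]
  tb <- matrix(theta[model$n_lam + seq_len(model$n_tb * (C - 1L))],
               nrow = model$n_tb, byrow = TRUE)
  kappa_f <- theta[model$npar - 1L]
  phi_f <- exp(theta[model$npar])
  taus <- theta_to_tau_rows(tb)
  g <- function(row, kappa, phi) {
    list(loadings = lam[model$lam_map[row, ]],
         thresholds = taus[model$tau_map[row, ], , drop = FALSE],
         factor_mean = kappa, factor_variance = phi)
  }
  list(r = g(1, 0, 1), f = g(2, kappa_f, phi_f))
}

# model-implied stacked statistics (standardized thresholds then lower-tri
# polychoric correlations, reference group first); closure precomputes the
# index bookkeeping so the per-evaluation cost stays minimal
ccfa_implied_fun <- function(model) {
  J <- model$J; C <- model$C
  n_lam <- model$n_lam; n_tb <- model$n_tb; npar <- model$npar
  tau_idx <- n_lam + seq_len(n_tb * (C - 1L))
  lam_r <- model$lam_map[1, ]; lam_f <- model$lam_map[2, ]
  tau_r <- model$tau_map[1, ]; tau_f <- model$tau_map[2, ]
  lt <- lower.tri(diag(J))
  imp <- function(lam, tau, kappa, phi) {
    sd_j <- sqrt(lam^2 * phi + 1)
    taustd <- (tau - lam * kappa) / sd_j
    corr <- (tcrossprod(lam) * phi) / tcrossprod(sd_j)
    c(as.vector(t(taustd)), corr[lt])
  }
  function(theta) {
    lam <- theta[seq_len(n_lam)]
    tb <- matrix(theta[tau_idx], nrow = n_tb, byrow = TRUE)
    taus <- theta_to_tau_rows(tb)
    c(imp(lam[lam_r], taus[tau_r, , drop = FALSE], 0, 1),
      imp(lam[lam_f], taus[tau_f, , drop = FALSE],
          theta[npar - 1L], exp(theta[npar])))
  }
}

ccfa_start <- function(model, ps) {
  r <- ps$groups$r
  ev <- eigen(r$rho, symmetric = TRUE)
  lam_std <- pmin(pmax(abs(ev$vectors[, 1]) * sqrt(max(ev$values[1], 0)),
                       0.10), 0.95)
  lam_t <- lam_std / sqrt(1 - lam_std^2)
  scale_t <- sqrt(1 + lam_t^2)
  tau_r <- r$tau * scale_t
  tau_f <- ps$groups$f$tau * scale_t
  tau_avg <- (tau_r + tau_f) / 2
  J <- model$J
  lam <- numeric(model$n_lam)
  tbl <- matrix(0, model$n_tb, model$C - 1L)
  for (row in 1:2) {
    src_tau <- if (row == 1) tau_r else tau_f
    for (j in seq_len(J)) {
      id <- model$lam_map[row, j]
      lam[id] <- lam_t[j]
      tid <- model$tau_map[row, j]
      tbl[tid, ] <- if (model$tau_map[1, j] == model$tau_map[2, j])
        tau_avg[j, ] else src_tau[j, ]
    }
  }
  th_tau <- t(apply(tbl, 1, tau_to_theta))
  if (model$C == 2L) th_tau <- matrix(th_tau, ncol = 1L)
  c(lam, as.vector(t(th_tau)), 0, 0)
}

# analytic Jacobian of the model-implied statistics with respect to theta;
# closure mirrors ccfa_implied_fun. Row order: per group, thresholds
# item-major then lower-triangle correlations; column order: loadings, tau
# blocks (tau1/log-gap metric), focal mean, log focal variance.
ccfa_jacobian_fun <- function(model) {
  J <- model$J; C <- model$C
  n_lam <- model$n_lam; n_tb <- model$n_tb; npar <- model$npar
  tau_idx <- n_lam + seq_len(n_tb * (C - 1L))
  pairs <- which(lower.tri(diag(J)), arr.ind = TRUE)
  n_thr <- J * (C - 1L)
  m_g <- n_thr + nrow(pairs)
  thr_row <- function(j) (j - 1L) * (C - 1L) + seq_len(C - 1L)
  tau_col <- function(b) n_lam + (b - 1L) * (C - 1L) + seq_len(C - 1L)

  function(theta) {
    lam <- theta[seq_len(n_lam)]
    tb <- matrix(theta[tau_idx], nrow = n_tb, byrow = TRUE)
    taus <- theta_to_tau_rows(tb)
    Jac <- matrix(0, 2L * m_g, npar)
    for (g in 1:2) {
      lam_g <- lam[model$lam_map[g, ]]
      tau_g <- taus[model$tau_map[g, ], , drop = FALSE]
      kap <- if (g == 1L) 0 else theta[npar - 1L]
      phi <- if (g == 1L) 1 else exp(theta[npar])
      s2 <- lam_g^2 * phi + 1
      s <- sqrt(s2)
      tstd <- (tau_g - lam_g * kap) / s
      off <- (g - 1L) * m_g
      for (j in seq_len(J)) {
        rows <- off + thr_row(j)
        lam_id <- model$lam_map[g, j]
        # d taustd / d lambda_j
        Jac[rows, lam_id] <- Jac[rows, lam_id] +
          (-kap / s[j] - tstd[j, ] * lam_g[j] * phi / s2[j])
        # d taustd / d tau-block params
        b <- model$tau_map[g, j]
        cols <- tau_col(b)
        Jac[rows, cols[1]] <- Jac[rows, cols[1]] + 1 / s[j]
        if (C > 2L) {
          for (m in 2:(C - 1L)) {
            sel <- rows[m:(C - 1L)]
            Jac[sel, cols[m]] <- Jac[sel, cols[m]] +
              exp(tb[b, m]) / s[j]
          }
        }
        if (g == 2L) {
          Jac[rows, npar - 1L] <- Jac[rows, npar - 1L] - lam_g[j] / s[j]
          Jac[rows, npar] <- Jac[rows, npar] +
            (-tstd[j, ] * lam_g[j]^2 * phi / (2 * s2[j])) # d/dlogphi = phi d/dphi
        }
      }
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        row <- off + n_thr + k
        cr <- lam_g[i] * lam_g[j] * phi / (s[i] * s[j])
        di <- lam_g[j] * phi / (s[i] * s[j]) - cr * lam_g[i] * phi / s2[i]
        dj <- lam_g[i] * phi / (s[i] * s[j]) - cr * lam_g[j] * phi / s2[j]
        ci <- model$lam_map[g, i]; cj <- model$lam_map[g, j]
        Jac[row, ci] <- Jac[row, ci] + di
        Jac[row, cj] <- Jac[row, cj] + dj
        if (g == 2L) {
          dphi <- lam_g[i] * lam_g[j] / (s[i] * s[j]) -
            cr * (lam_g[i]^2 / (2 * s2[i]) + lam_g[j]^2 / (2 * s2[j]))
          Jac[row, npar] <- Jac[row, npar] + dphi * phi
        }
      }
    }
    Jac
  }
}

# warm start for a step-down model from a fitted scalar model: the freed
# item's focal parameters start at the shared estimates
stepdown_start <- function(model, scalar_fit) {
  th <- scalar_fit$theta
  if (is.null(th)) return(NULL)
  J <- model$J; C <- model$C
  lam <- th[seq_len(J)]
  taub <- th[J + seq_len(J * (C - 1L))]
  tail2 <- th[length(th) - 1:0]
  if (model$which == "loading") {
    c(lam, lam[model$item], taub, tail2)
  } else {
    blk <- taub[(model$item - 1L) * (C - 1L) + seq_len(C - 1L)]
    c(lam, taub, blk, tail2)
  }
}

# U = W - W Delta (Delta' W Delta)^{-1} Delta' W  with diagonal W
ccfa_umatrix <- function(w, Delta) {
  WD <- w * Delta
  A <- crossprod(Delta, WD)
  Ai <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ai)) return(NULL)
  diag(w) - WD %*% Ai %*% t(WD)
}

#' Fit a multiple-group categorical CFA by diagonally weighted least squares
#'
#' Second stage of the two-step estimator: minimizes the weighted squared
#' distance between the first-stage statistics (standardized thresholds and
#' polychoric correlations of both groups) and their model-implied
#' counterparts, using the inverse diagonal of the asymptotic covariance
#' matrix as weights. The full covariance matrix is then used to compute a
#' mean-and-variance-adjusted (scaled-and-shifted) chi-square statistic.
#'
#' Identification follows the minimal anchor constraints: all unique
#' variances fixed to 1 in both groups, reference factor standard normal,
#' focal factor mean and variance free, and the anchor item's loading and
#' thresholds constrained equal across groups in every constraint pattern.
#'
#' @param data An `mi_data` object, or a precomputed [polychoric_summary()]
#'   (then `n_obs` is taken from it).
#' @param pattern Constraint pattern: `"configural"` (only the anchor is
#'   constrained), `"metric"` (all loadings equal), `"scalar"` (loadings and
#'   thresholds equal), `"stepdown"` (scalar with one item's loading or
#'   thresholds freed in the focal group), `"null"` (independence baseline:
#'   zero correlations, group-specific free thresholds).
#' @param item,which For `pattern = "stepdown"`: the freed item and whether
#'   its `"loading"` or `"thresholds"` are released.
#' @param adjust `"scaled_shifted"` (first two moments matched at the model
#'   df; reported df is the integer model df) or `"mean_var"` (Satterthwaite:
#'   statistic divided by the scale factor, non-integer df).
#' @param anchor Anchor item index (default 1).
#' @param start Optional warm start: a numeric parameter vector, or a fitted
#'   scalar `mi_ccfa_fit` when fitting a step-down model.
#' @return Object of class `mi_ccfa_fit` with elements `estimates` (per-group
#'   loadings/thresholds on the unit-unique-variance scale, focal mean and
#'   variance), `chisq` (adjusted statistic), `chisq_unscaled`, `df`, `p`,
#'   `converged`, `n_obs`, and internal matrices used by [chisq_diff()].
#' @export
fit_mgccfa <- function(data, pattern = "configural", item = NULL,
                       which = NULL, adjust = c("scaled_shifted", "mean_var"),
                       anchor = 1L, start = NULL) {
  adjust <- match.arg(adjust)
  ps <- if (inherits(data, "mi_polysum")) data else polychoric_summary(data)
  J <- ps$n_items; C <- ps$n_categories
  model <- ccfa_model(J, C, pattern, item, which, anchor)
  s <- c(ps$groups$r$stat, ps$groups$f$stat)
  G <- matrix(0, length(s), length(s))
  m1 <- length(ps$groups$r$stat)
  G[seq_len(m1), seq_len(m1)] <- ps$groups$r$acov
  G[m1 + seq_len(m1), m1 + seq_len(m1)] <- ps$groups$f$acov
  w <- 1 / pmax(diag(G), 1e-12)
  n_obs <- ps$groups$r$n + ps$groups$f$n
  df <- length(s) - model$npar

  if (model$pattern == "null") {
    # thresholds fitted exactly per group; residuals are the correlations
    n_tau <- J * (C - 1L)
    mhat <- s
    mhat[c(n_tau + seq_len(m1 - n_tau), m1 + n_tau + seq_len(m1 - n_tau))] <- 0
    e <- s - mhat
    Delta <- matrix(0, length(s), model$npar)
    idx <- c(seq_len(n_tau), m1 + seq_len(n_tau))
    Delta[cbind(idx, seq_len(model$npar))] <- 1
    theta <- NULL
    conv <- TRUE
    obj_val <- sum(w * e^2)
  } else {
    mfun <- ccfa_implied_fun(model)
    jfun <- ccfa_jacobian_fun(model)
    obj <- function(th) {
      e <- s - mfun(th)
      sum(w * e^2)
    }
    gr <- function(th) {
      e <- s - mfun(th)
      -2 * crossprod(jfun(th), w * e)[, 1]
    }
    st <- start
    if (inherits(start, "mi_ccfa_fit")) {
      st <- if (start$pattern == "scalar" && model$pattern == "stepdown")
        stepdown_start(model, start) else NULL
    }
    if (is.null(st)) st <- ccfa_start(model, ps)
    opt <- nlminb(st, obj, gradient = gr,
                  control = list(iter.max = 500, eval.max = 2000,
                                 rel.tol = 1e-9))
    theta <- opt$par
    pars <- ccfa_pars(model, theta)
    conv <- opt$convergence == 0 &&
      is.finite(opt$objective) &&
      pars$f$factor_variance > 1e-3 && pars$f$factor_variance < 1e3 &&
      abs(pars$f$factor_mean) < 10 &&
      max(abs(c(pars$r$loadings, pars$f$loadings))) < 20
    e <- s - mfun(theta)
    Delta <- jfun(theta)
    obj_val <- opt$objective
  }

  U <- ccfa_umatrix(w, Delta)
  if (is.null(U)) {
    conv <- FALSE
    U <- diag(w)
  }
  UG <- U %*% G
  tr1 <- sum(diag(UG))
  tr2 <- sum(UG * t(UG))
  T_u <- sum(w * e^2)
  if (tr2 <= 0) conv <- FALSE
  if (adjust == "scaled_shifted") {
    a <- sqrt(df / max(tr2, 1e-300))
    chisq <- max(a * T_u + df - a * tr1, 0)
    df_rep <- df
  } else {
    cc <- tr2 / tr1
    chisq <- T_u / cc
    df_rep <- tr1^2 / tr2
  }
  p <- pchisq(chisq, df_rep, lower.tail = FALSE)

  est <- if (is.null(theta)) NULL else ccfa_pars(model, theta)
  structure(
    list(pattern = model$pattern, item = model$item, which = model$which,
         estimates = est, theta = theta,
         chisq = chisq, chisq_unscaled = T_u, df = df,
         df_reported = df_rep, p = p, converged = conv, n_obs = n_obs,
         n_groups = 2L, adjust = adjust, UG = UG, npar = model$npar),
    class = "mi_ccfa_fit"
  )
}

#' @export
print.mi_ccfa_fit <- function(x, ...) {
  cat(sprintf("MG-CCFA fit (%s%s): chisq = %.3f, df = %s, p = %.4f, %s\n",
              x$pattern,
              if (!is.null(x$item)) sprintf(", item %d %s", x$item, x$which)
              else "",
              x$chisq, format(x$df_reported), x$p,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Scaled chi-square difference test between nested DWLS fits
#'
#' Compares a restricted model against a less restricted model fitted to the
#' same first-stage statistics. The default second-order construction forms
#' the unscaled statistic difference and rescales it with the difference of
#' the two models' correction matrices (`U_restricted - U_free`), matching
#' the first two moments at the df difference; the statistic is floored at 0.
#' `method = "naive"` subtracts the adjusted statistics directly.
#'
#' @param fit_restricted,fit_free `mi_ccfa_fit` objects, restricted model
#'   first (larger df).
#' @param method `"scaled_shifted"` or `"naive"`.
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_diff <- function(fit_restricted, fit_free,
                       method = c("scaled_shifted", "naive")) {
  method <- match.arg(method)
  df_d <- fit_restricted$df - fit_free$df
  if (df_d <= 0) stop("models are not nested (df difference <= 0)",
                      call. = FALSE)
  if (method == "naive" || is.null(fit_restricted$UG)) {
    stat <- max(fit_restricted$chisq - fit_free$chisq, 0)
  } else {
    T_d <- max(fit_restricted$chisq_unscaled - fit_free$chisq_unscaled, 0)
    UDG <- fit_restricted$UG - fit_free$UG
    tr1 <- sum(diag(UDG))
    tr2 <- sum(UDG * t(UDG))
    if (tr2 <= 1e-12) {
      stat <- max(fit_restricted$chisq - fit_free$chisq, 0)
    } else {
      a <- sqrt(df_d / tr2)
      stat <- max(a * T_d + df_d - a * tr1, 0)
    }
  }
  list(statistic = stat, df = df_d,
       p = pchisq(stat, df_d, lower.tail = FALSE))
}

#' Multiple-group RMSEA
#'
#' Conventional multi-group form
#' `sqrt(G) * sqrt(max((chisq - df) / (df * (N - 1)), 0))` with `N` the total
#' sample size across groups. `form = "printed"` uses the variant
#' `sqrt(G) * sqrt(max(chisq/df - 1/(N-1), 0))` (not scale-free; retained as
#' a switch).
#'
#' @param chisq,df Test statistic and degrees of freedom (an `mi_ccfa_fit`
#'   may be passed as `chisq`).
#' @param n_total Total number of observations across groups.
#' @param n_groups Number of groups.
#' @param form `"conventional"` or `"printed"`.
#' @return RMSEA value (>= 0).
#' @export
rmsea <- function(chisq, df = NULL, n_total = NULL, n_groups = 2,
                  form = c("conventional", "printed")) {
  form <- match.arg(form)
  if (inherits(chisq, "mi_ccfa_fit")) {
    fit <- chisq
    if (is.null(n_total)) n_total <- fit$n_obs
    df <- fit$df
    chisq <- fit$chisq
  }
  if (df <= 0) stop("RMSEA undefined for df = 0", call. = FALSE)
  core <- if (form == "conventional")
    (chisq - df) / (df * (n_total - 1))
  else chisq / df - 1 / (n_total - 1)
  sqrt(n_groups) * sqrt(max(core, 0))
}

#' Comparative fit index
#'
#' `CFI = 1 - max(chisq - df, 0) / max(chisq_null - df_null, chisq - df, 0)`
#' relative to the independence baseline (zero inter-item correlations,
#' group-specific free thresholds), capped to `[0, 1]`.
#'
#' @param chisq,df Target model statistic and df (or an `mi_ccfa_fit`).
#' @param null_chisq,null_df Baseline model statistic and df (or the
#'   baseline `mi_ccfa_fit` as `null_chisq`).
#' @return CFI value in `[0, 1]`.
#' @export
cfi <- function(chisq, df = NULL, null_chisq = NULL, null_df = NULL) {
  if (inherits(chisq, "mi_ccfa_fit")) {
    df <- chisq$df; chisq <- chisq$chisq
  }
  if (inherits(null_chisq, "mi_ccfa_fit")) {
    null_df <- null_chisq$df; null_chisq <- null_chisq$chisq
  }
  num <- max(chisq - df, 0)
  den <- max(null_chisq - null_df, num)
  if (den == 0) return(1)
  max(0, min(1, 1 - num / den))
}

#' Configural-metric-scalar invariance sequence
#'
#' Fits the configural, metric, scalar and independence-baseline models to a
#' two-group ordinal dataset and computes the scale-level tests: the scaled
#' chi-square difference, the change in RMSEA and the change in CFI between
#' metric and configural (loadings test) and between scalar and metric
#' (thresholds test). Deltas are constrained-minus-less-constrained, so
#' positive `delta_rmsea` and negative `delta_cfi` indicate worsening fit.
#'
#' @param data `mi_data` or `mi_polysum`.
#' @param adjust Test-statistic adjustment, see [fit_mgccfa()].
#' @param diff_method Difference-test construction, see [chisq_diff()].
#' @param rmsea_form See [rmsea()].
#' @return Object of class `mi_ccfa_sequence`: the four fits, a `tests` data
#'   frame (one row per tested parameter type) and a `converged` flag.
#' @export
invariance_sequence <- function(data, adjust = "scaled_shifted",
                                diff_method = "scaled_shifted",
                                rmsea_form = "conventional") {
  ps <- if (inherits(data, "mi_polysum")) data else polychoric_summary(data)
  fits <- list(
    configural = fit_mgccfa(ps, "configural", adjust = adjust),
    metric = fit_mgccfa(ps, "metric", adjust = adjust),
    scalar = fit_mgccfa(ps, "scalar", adjust = adjust),
    null = fit_mgccfa(ps, "null", adjust = adjust)
  )
  n_total <- fits$configural$n_obs
  idx <- function(fit) {
    c(rmsea = rmsea(fit, n_total = n_total, form = rmsea_form),
      cfi = cfi(fit, null_chisq = fits$null))
  }
  ix <- lapply(fits[1:3], idx)
  row <- function(parameter, restricted, free) {
    d <- chisq_diff(fits[[restricted]], fits[[free]], method = diff_method)
    data.frame(parameter = parameter, statistic = d$statistic, df = d$df,
               p = d$p,
               delta_rmsea = ix[[restricted]]["rmsea"] - ix[[free]]["rmsea"],
               delta_cfi = ix[[restricted]]["cfi"] - ix[[free]]["cfi"],
               row.names = NULL)
  }
  tests <- rbind(row("loadings", "metric", "configural"),
                 row("thresholds", "scalar", "metric"))
  structure(
    list(fits = fits, tests = tests, indices = ix,
         converged = all(vapply(fits, `[[`, logical(1), "converged"))),
    class = "mi_ccfa_sequence"
  )
}

#' @export
print.mi_ccfa_sequence <- function(x, ...) {
  cat("MG-CCFA invariance sequence",
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(x$tests, digits = 4)
  invisible(x)
}

#' Item-level step-down test for one item
#'
#' Compares the fully constrained (scalar) model with the same model in which
#' the focal-group loading (df = 1) or threshold vector (df = C-1) of one
#' non-anchor item is freed, returning the scaled chi-square difference and
#' the RMSEA/CFI changes (scalar minus freed model).
#'
#' @param data `mi_data` or `mi_polysum`.
#' @param item Non-anchor item index.
#' @param which `"loading"` or `"thresholds"`.
#' @param scalar_fit,null_fit Optional precomputed fits (reused across items).
#' @inheritParams invariance_sequence
#' @return List with `statistic`, `df`, `p`, `delta_rmsea`, `delta_cfi`,
#'   `converged`, and the freed-model fit.
#' @export
stepdown_item_test <- function(data, item, which = c("loading", "thresholds"),
                               scalar_fit = NULL, null_fit = NULL,
                               adjust = "scaled_shifted",
                               diff_method = "scaled_shifted",
                               rmsea_form = "conventional") {
  which <- match.arg(which)
  ps <- if (inherits(data, "mi_polysum")) data else polychoric_summary(data)
  if (is.null(scalar_fit)) scalar_fit <- fit_mgccfa(ps, "scalar",
                                                    adjust = adjust)
  if (is.null(null_fit)) null_fit <- fit_mgccfa(ps, "null", adjust = adjust)
  free_fit <- fit_mgccfa(ps, "stepdown", item = item, which = which,
                         adjust = adjust, start = scalar_fit)
  d <- chisq_diff(scalar_fit, free_fit, method = diff_method)
  n_total <- scalar_fit$n_obs
  list(
    statistic = d$statistic, df = d$df, p = d$p,
    delta_rmsea = rmsea(scalar_fit, n_total = n_total, form = rmsea_form) -
      rmsea(free_fit, n_total = n_total, form = rmsea_form),
    delta_cfi = cfi(scalar_fit, null_chisq = null_fit) -
      cfi(free_fit, null_chisq = null_fit),
    converged = scalar_fit$converged && free_fit$converged,
    fit = free_fit
  )
}
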