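#' Map categorical-factor-model parameters to graded-response parameters
#'
#' Under the unit-unique-variance identification the two parameterizations
#' are related by `alpha = lambda / sigma` and `delta_c = tau_c / lambda`.
#'
#' @param loading Factor loading `lambda`.
#' @param unique_sd Residual standard deviation `sigma` (> 0).
#' @param thresholds Factor-model thresholds `tau` (strictly increasing).
#' @return List with `discrimination` (`alpha`), `thresholds` (`delta`), and
#'   `intercepts` (`b = alpha * delta`, the probit slope-intercept form).
#' @export
map_ccfa_to_grm <- function(loading, unique_sd, thresholds) {
  if (unique_sd <= 0) stop("`unique_sd` must be positive", call. = FALSE)
  if (loading == 0)
    stop("mapping undefined for a zero loading", call. = FALSE)
  alpha <- loading / unique_sd
  delta <- thresholds / loading
  list(discrimination = alpha, thresholds = delta,
       intercepts = thresholds / unique_sd)
}

# category probabilities of one normal-ogive GRM item at quadrature nodes:
# P(X = c | eta) = Phi(a*eta - b_c) - Phi(a*eta - b_{c+1}); returns Q x C
grm_item_probs <- function(a, b, nodes) {
  cum <- cbind(1, pnorm(outer(a * nodes, b, `-`)), 0)
  pr <- cum[, -ncol(cum), drop = FALSE] - cum[, -1, drop = FALSE]
  pmax(pr, 1e-300)
}

# negative expected complete-data log-likelihood for one item given expected
# counts R (Q x C); theta = (log a, b1, log gaps)
grm_item_nll <- function(theta, R, nodes) {
  a <- exp(theta[1])
  b <- theta_to_tau(theta[-1])
  if (!is.finite(a) || !all(is.finite(b))) return(1e10)
  v <- -sum(R * log(grm_item_probs(a, b, nodes)))
  if (is.finite(v)) v else 1e10
}

# analytic gradient of grm_item_nll in the (log a, b1, log gaps) metric
grm_item_grad <- function(theta, R, nodes) {
  a <- exp(theta[1])
  b <- theta_to_tau(theta[-1])
  if (!is.finite(a) || !all(is.finite(b))) return(numeric(length(theta)))
  z <- outer(a * nodes, b, `-`)
  cum <- cbind(1, pnorm(z), 0)
  dens <- dnorm(z)                              # Q x (C-1)
  P <- pmax(cum[, -ncol(cum), drop = FALSE] - cum[, -1, drop = FALSE], 1e-300)
  W <- R / P                                    # Q x C
  C <- ncol(P)
  # d nll / d b_k
  g_b <- vapply(seq_len(C - 1L), function(k)
    sum(dens[, k] * (W[, k + 1L] - W[, k])), numeric(1))
  # d nll / d a
  dens0 <- cbind(0, dens, 0)
  dPda <- dens0[, -ncol(dens0), drop = FALSE] - dens0[, -1, drop = FALSE]
  g_a <- -sum(W * (nodes * dPda))
  # chain rule to (log a, b1, log gaps)
  g_theta_b <- numeric(C - 1L)
  g_theta_b[1] <- sum(g_b)
  if (C > 2L) {
    for (m in 2:(C - 1L))
      g_theta_b[m] <- exp(theta[m + 1L]) * sum(g_b[m:(C - 1L)])
  }
  g <- c(a * g_a, g_theta_b)
  if (all(is.finite(g))) g else numeric(length(theta))
}

#' Fit a multiple-group normal-ogive graded response model
#'
#' Marginal maximum likelihood via an EM algorithm on a fixed quadrature grid
#' (default 61 nodes on \[-6, 6\] in the reference metric). The reference
#' group's latent distribution is standard normal; the focal group's mean and
#' variance are free and updated from the posterior moments each cycle
#' (focal integration reuses the reference grid with renormalized normal
#' weights). All items are constrained equal across groups except an optional
#' freed item, whose loading (discrimination), thresholds, or both get
#' focal-specific values; the anchor item can never be freed.
#'
#' @param data An `mi_data` object.
#' @param freed `NULL` (fully constrained), or
#'   `list(item = k, what = "loading"|"thresholds"|"both")`; `item` may be a
#'   vector (e.g. the flagged set during score purification).
#' @param pooled If `TRUE`, all persons are treated as a single standard-
#'   normal group (used for one-shot latent scoring).
#' @param n_nodes Number of quadrature nodes.
#' @param tol Absolute convergence tolerance on the marginal log-likelihood.
#' @param max_cycles Maximum EM cycles.
#' @param anchor Anchor item index.
#' @param start Optional `mi_grm_fit` supplying warm-start parameter values
#'   (used when fitting augmented models after a constrained one).
#' @return Object of class `mi_grm_fit`: per-group `discrimination` and
#'   `intercepts` (slope-intercept form, with `delta = intercepts /
#'   discrimination`), `focal_mean`, `focal_variance`, `loglik`, `n_params`,
#'   `converged`, and the quadrature specification.
#' @export
fit_mg_grm <- function(data, freed = NULL, pooled = FALSE, n_nodes = 61L,
                       tol = 1e-6, max_cycles = 1000L, anchor = 1L,
                       start = NULL) {
  stopifnot(inherits(data, "mi_data"))
  X <- data$responses
  J <- ncol(X); C <- data$n_categories
  if (!is.null(freed)) {
    if (pooled) stop("`freed` has no meaning in a pooled fit", call. = FALSE)
    freed$what <- match.arg(freed$what, c("loading", "thresholds", "both"))
    if (anchor %in% freed$item)
      stop("the anchor item cannot be freed", call. = FALSE)
  }
  nodes <- seq(-6, 6, length.out = n_nodes)
  grp <- if (pooled) factor(rep("r", nrow(X)), levels = "r") else data$group
  glev <- levels(grp)
  # collapse to unique response patterns per group (the likelihood only
  # depends on the pattern); map indexes persons back into patterns
  Xg <- vector("list", length(glev))
  wg <- vector("list", length(glev))
  map_g <- vector("list", length(glev))
  for (gi in seq_along(glev)) {
    Xi <- X[grp == glev[gi], , drop = FALSE]
    pid <- as.vector(Xi %*% C^(seq_len(J) - 1L))
    u <- !duplicated(pid)
    Xg[[gi]] <- Xi[u, , drop = FALSE]
    key <- match(pid, pid[u])
    wg[[gi]] <- tabulate(key, nbins = sum(u))
    map_g[[gi]] <- key
  }
  ng <- vapply(map_g, length, integer(1))
  np <- vapply(Xg, nrow, integer(1))

  # starting values: common item parameters from pooled univariate thresholds
  a <- rep(1, J)
  B <- matrix(0, J, C - 1L)
  for (j in seq_len(J)) {
    cnt <- tabulate(X[, j] + 1L, nbins = C)
    if (any(cnt == 0))
      stop(errorCondition("empty response category",
                          class = c("ordmi_degenerate",
                                    "ordmi_nonconvergence")))
    tauj <- univariate_thresholds(cnt)
    B[j, ] <- tauj * sqrt(1 + a[j]^2)
  }
  # per-group parameter views: row 1 reference, row 2 focal
  a_g <- rbind(a, a)
  B_g <- list(B, B)
  mu_f <- 0; var_f <- 1
  if (inherits(start, "mi_grm_fit")) {
    a_g <- rbind(start$discrimination$r, start$discrimination$f)
    B_g <- list(start$intercepts$r, start$intercepts$f)
    if (!pooled && !is.na(start$focal_mean)) {
      mu_f <- start$focal_mean
      var_f <- start$focal_variance
    }
  }

  free_load <- !is.null(freed) && freed$what %in% c("loading", "both")
  free_thr <- !is.null(freed) && freed$what %in% c("thresholds", "both")

  loglik_prev <- -Inf
  dll_prev <- Inf
  converged <- FALSE
  for (cycle in seq_len(max_cycles)) {
    # E-step
    prior <- list(
      r = {
        w <- dnorm(nodes); w / sum(w)
      },
      f = {
        w <- dnorm(nodes, mu_f, sqrt(var_f)); w / sum(w)
      }
    )
    ll <- 0
    post <- vector("list", length(glev))
    for (gi in seq_along(glev)) {
      Xi <- Xg[[gi]]
      logL <- matrix(0, n_nodes, np[gi])
      for (j in seq_len(J)) {
        lp <- log(grm_item_probs(a_g[gi, j], B_g[[gi]][j, ], nodes))
        logL <- logL + lp[, Xi[, j] + 1L, drop = FALSE]
      }
      wL <- prior[[gi]] * exp(logL)
      colsum <- colSums(wL)
      ll <- ll + sum(wg[[gi]] * log(colsum))
      # pattern-weighted posterior (each column scaled by pattern count)
      post[[gi]] <- sweep(wL, 2, wg[[gi]] / colsum, `*`)
    }
    if (!is.finite(ll)) break

    # M-step: items
    for (j in seq_len(J)) {
      R_g <- lapply(seq_along(glev), function(gi) {
        Xi <- Xg[[gi]]
        R <- matrix(0, n_nodes, C)
        for (cc in 0:(C - 1L)) {
          sel <- Xi[, j] == cc
          if (any(sel))
            R[, cc + 1L] <- rowSums(post[[gi]][, sel, drop = FALSE])
        }
        R
      })
      upd <- function(R, th0) {
        o <- nlminb(th0, grm_item_nll, gradient = grm_item_grad, R = R,
                    nodes = nodes, control = list(iter.max = 25))
        if (all(is.finite(o$par))) o$par else th0
      }
      if (length(glev) == 1L || is.null(freed) || !(j %in% freed$item)) {
        R <- Reduce(`+`, R_g)
        th <- upd(R, c(log(a_g[1, j]), tau_to_theta(B_g[[1]][j, ])))
        for (gi in seq_along(glev)) {
          a_g[gi, j] <- exp(th[1])
          B_g[[gi]][j, ] <- theta_to_tau(th[-1])
        }
      } else {
        # freed item: focal-specific loading and/or thresholds, jointly
        th0 <- c(log(a_g[1, j]), tau_to_theta(B_g[[1]][j, ]),
                 if (free_load) log(a_g[2, j]),
                 if (free_thr) tau_to_theta(B_g[[2]][j, ]))
        nb <- C - 1L
        split_th <- function(th) {
          a_r <- th[1]; b_r <- th[2:(1 + nb)]
          k <- 1 + nb
          a_f <- if (free_load) th[k + 1] else a_r
          if (free_load) k <- k + 1
          b_f <- if (free_thr) th[(k + 1):(k + nb)] else b_r
          list(r = c(a_r, b_r), f = c(a_f, b_f))
        }
        nll <- function(th) {
          p <- split_th(th)
          grm_item_nll(p$r, R_g[[1]], nodes) +
            grm_item_nll(p$f, R_g[[2]], nodes)
        }
        grd <- function(th) {
          p <- split_th(th)
          g1 <- grm_item_grad(p$r, R_g[[1]], nodes)
          g2 <- grm_item_grad(p$f, R_g[[2]], nodes)
          ga <- if (free_load) c(g1[1], g2[1]) else g1[1] + g2[1]
          gb <- if (free_thr) c(g1[-1], g2[-1]) else g1[-1] + g2[-1]
          if (free_load && free_thr)
            c(g1[1], g1[-1], g2[1], g2[-1])
          else if (free_load) c(g1[1], gb, g2[1])
          else c(ga, g1[-1], g2[-1])
        }
        o <- nlminb(th0, nll, gradient = grd,
                    control = list(iter.max = 25))
        th <- if (all(is.finite(o$par))) o$par else th0
        a_g[1, j] <- exp(th[1]); B_g[[1]][j, ] <- theta_to_tau(th[2:(1 + nb)])
        k <- 1 + nb
        if (free_load) { a_g[2, j] <- exp(th[k + 1]); k <- k + 1 }
        else a_g[2, j] <- a_g[1, j]
        B_g[[2]][j, ] <- if (free_thr) theta_to_tau(th[(k + 1):(k + nb)])
        else B_g[[1]][j, ]
      }
    }
    # M-step: focal latent distribution
    if (length(glev) == 2L) {
      pf <- post[[2]]
      wq <- rowSums(pf) / ng[2]
      mu_f <- sum(wq * nodes)
      var_f <- sum(wq * (nodes - mu_f)^2)
      var_f <- max(var_f, 1e-4)
    }
    # Aitken-accelerated stopping: with geometric EM progress at rate r the
    # remaining gain is approximately (ll_k - ll_{k-1}) * r / (1 - r)
    dll <- ll - loglik_prev
    rate <- if (cycle > 2L && dll_prev > 0) dll / dll_prev else NA_real_
    gap <- if (is.finite(rate) && rate > 0 && rate < 1)
      dll * rate / (1 - rate) else dll
    if (abs(gap) < tol && abs(dll) < sqrt(tol)) {
      converged <- TRUE
      loglik_prev <- ll
      break
    }
    dll_prev <- dll
    loglik_prev <- ll
  }
  ok <- is.finite(loglik_prev) && all(is.finite(a_g)) &&
    all(vapply(B_g, function(b) all(is.finite(b)), logical(1))) &&
    is.finite(mu_f) && is.finite(var_f) &&
    max(a_g) <= 50 && abs(mu_f) <= 5 && var_f <= 25
  if (!ok) converged <- FALSE

  n_freed <- if (is.null(freed)) 0L else length(freed$item)
  n_params <- J * C + (if (pooled) 0L else 2L) +
    n_freed * ((if (free_load) 1L else 0L) +
                 (if (free_thr) C - 1L else 0L))

  # EAP scores in data row order
  eap <- numeric(nrow(X))
  prior <- list(r = dnorm(nodes) / sum(dnorm(nodes)),
                f = dnorm(nodes, mu_f, sqrt(var_f)) /
                  sum(dnorm(nodes, mu_f, sqrt(var_f))))
  for (gi in seq_along(glev)) {
    Xi <- Xg[[gi]]
    logL <- matrix(0, n_nodes, np[gi])
    for (j in seq_len(J)) {
      lp <- log(grm_item_probs(a_g[gi, j], B_g[[gi]][j, ], nodes))
      logL <- logL + lp[, Xi[, j] + 1L, drop = FALSE]
    }
    wL <- prior[[gi]] * exp(logL)
    eap_pat <- colSums(wL * nodes) / colSums(wL)
    eap[grp == glev[gi]] <- eap_pat[map_g[[gi]]]
  }

  structure(
    list(
      discrimination = list(r = a_g[1, ], f = a_g[2, ]),
      intercepts = list(r = B_g[[1]], f = B_g[[2]]),
      delta = list(r = B_g[[1]] / a_g[1, ], f = B_g[[2]] / a_g[2, ]),
      focal_mean = if (pooled) NA_real_ else mu_f,
      focal_variance = if (pooled) NA_real_ else var_f,
      loglik = loglik_prev, n_params = n_params, converged = converged,
      cycles = cycle, eap = eap, freed = freed, pooled = pooled,
      n_nodes = n_nodes, anchor = anchor
    ),
    class = "mi_grm_fit"
  )
}

#' @export
print.mi_grm_fit <- function(x, ...) {
  cat(sprintf(
    "MG-noGRM fit (%s): loglik = %.3f, %d parameters, %d EM cycles, %s\n",
    if (x$pooled) "pooled" else if (is.null(x$freed)) "constrained"
    else sprintf("item %d %s freed", x$freed$item, x$freed$what),
    x$loglik, x$n_params, x$cycles,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Likelihood-ratio DIF test for one item
#'
#' Compares the fully constrained two-group model (compact model) with an
#' augmented model in which the focal-group loading (`df = 1`) or threshold
#' vector (`df = C-1`, or 1 if `df1 = TRUE`) of one non-anchor item is freed:
#' `G2 = -2 lnL_C + 2 lnL_A`, referred to a chi-square distribution.
#'
#' @param data An `mi_data` object.
#' @param item Non-anchor item to test.
#' @param which `"loading"` (nonuniform DIF) or `"thresholds"` (uniform DIF).
#' @param constrained_fit Optional precomputed constrained fit (reused across
#'   items).
#' @param df1 Refer the threshold test to 1 df regardless of the number of
#'   freed parameters (not recommended; kept as a switch).
#' @param ... Passed to [fit_mg_grm()].
#' @return List with `statistic` (G2), `df`, `p`, `converged`, and both fits.
#' @export
grm_lrt <- function(data, item, which = c("loading", "thresholds"),
                    constrained_fit = NULL, df1 = FALSE, ...) {
  which <- match.arg(which)
  if (is.null(constrained_fit)) constrained_fit <- fit_mg_grm(data, ...)
  aug <- fit_mg_grm(data, freed = list(item = item, what = which),
                    start = constrained_fit, ...)
  g2 <- max(2 * (aug$loglik - constrained_fit$loglik), 0)
  df <- if (which == "loading" || df1) 1L else data$n_categories - 1L
  list(statistic = g2, df = df, p = pchisq(g2, df, lower.tail = FALSE),
       converged = constrained_fit$converged && aug$converged,
       constrained = constrained_fit, augmented = aug)
}
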