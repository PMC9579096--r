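#' @importFrom stats qnorm dnorm pnorm pchisq optimize cov
NULL

# Bivariate standard-normal CDF on a threshold grid.
# Returns the (K+2) x (L+2) matrix of Phi2 values at all crossings of
# c(-Inf, tx, Inf) and c(-Inf, ty, Inf); boundary rows/cols handled in
# closed form so only finite pairs hit the Fortran integrator.
phi2_grid <- function(tx, ty, rho) {
  ax <- c(-Inf, tx, Inf)
  ay <- c(-Inf, ty, Inf)
  K <- length(ax); L <- length(ay)
  out <- matrix(0, K, L)
  out[K, ] <- pnorm(ay)       # Phi2(Inf, b) = Phi(b)
  out[, L] <- pnorm(ax)
  out[1, ] <- 0; out[, 1] <- 0
  out[K, L] <- 1
  if (K > 2 && L > 2) {
    S <- matrix(c(1, rho, rho, 1), 2)
    zero <- c(0, 0); ninf <- c(-Inf, -Inf)
    for (xi in 2:(K - 1))
      for (yi in 2:(L - 1))
        out[xi, yi] <- mnormt::biv.nt.prob(Inf, ninf, c(ax[xi], ay[yi]),
                                           zero, S)
    }
  out
}

# Cell probabilities pi_ab(rho) for a C1 x C2 table with fixed thresholds.
cell_probs <- function(tx, ty, rho) {
  G <- phi2_grid(tx, ty, rho)
  K <- nrow(G); L <- ncol(G)
  G[-1, -1] - G[-K, -1] - G[-1, -L] + G[-K, -L]
}

# d pi_ab / d rho: bivariate density summed over cell corners with signs
# (d Phi2(h,k;rho)/d rho = phi2(h,k;rho); zero at infinite corners).
cell_probs_drho <- function(tx, ty, rho) {
  ax <- c(-Inf, tx, Inf)
  ay <- c(-Inf, ty, Inf)
  K <- length(ax); L <- length(ay)
  D <- matrix(0, K, L)
  fin <- expand.grid(x = seq_len(K), y = seq_len(L))
  ok <- is.finite(ax[fin$x]) & is.finite(ay[fin$y])
  if (any(ok)) {
    h <- ax[fin$x[ok]]; k <- ay[fin$y[ok]]
    om <- 1 - rho^2
    dens <- exp(-(h^2 - 2 * rho * h * k + k^2) / (2 * om)) /
      (2 * pi * sqrt(om))
    D[cbind(fin$x[ok], fin$y[ok])] <- dens
  }
  D[-1, -1] - D[-K, -1] - D[-1, -L] + D[-K, -L]
}

#' Univariate thresholds from category counts
#'
#' Estimates the normal-ogive thresholds of one ordinal item as
#' `qnorm(cumulative proportions)`. An empty category anywhere in the count
#' vector yields a non-finite or tied threshold and signals a degenerate-
#' category error (condition class `ordmi_degenerate`); the simulator treats
#' this as replication-level nonconvergence.
#'
#' @param counts Integer vector of per-category counts (length C).
#' @return Numeric vector of C-1 strictly increasing thresholds.
#' @export
univariate_thresholds <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0)
    stop("invalid category counts", call. = FALSE)
  if (any(counts == 0))
    stop(errorCondition("empty response category",
                        class = c("ordmi_degenerate", "ordmi_nonconvergence")))
  p <- cumsum(counts) / sum(counts)
  qnorm(p[-length(p)])
}

#' Pairwise polychoric correlation (two-step ML)
#'
#' Maximizes the bivariate-normal cell likelihood
#' `sum n_ab log pi_ab(rho)` over `rho` with the univariate thresholds held
#' fixed at their first-stage estimates (the first step of DWLS estimation).
#' Bounded scalar maximization on (-0.999, 0.999), tolerance 1e-8; an
#' estimate at the boundary signals nonconvergence
#' (condition class `ordmi_nonconvergence`).
#'
#' @param pair_table C x C contingency table of the two items.
#' @param thresholds_x,thresholds_y Fixed threshold vectors of the two items.
#' @return The ML estimate of the latent correlation.
#' @export
polychoric_rho <- function(pair_table, thresholds_x, thresholds_y) {
  n <- pair_table
  score <- function(r) {
    p <- pmax(cell_probs(thresholds_x, thresholds_y, r), 1e-300)
    dp <- cell_probs_drho(thresholds_x, thresholds_y, r)
    sum(n * dp / p)
  }
  # safeguarded secant iteration on the score equation; starting value from
  # the Pearson correlation of the normal scores implied by the thresholds
  mids_x <- qnorm((pnorm(c(-Inf, thresholds_x)) +
                     pnorm(c(thresholds_x, Inf))) / 2)
  mids_y <- qnorm((pnorm(c(-Inf, thresholds_y)) +
                     pnorm(c(thresholds_y, Inf))) / 2)
  N <- sum(n)
  mx <- sum(n * rep(mids_x, ncol(n))) / N   # rows index x
  my <- sum(n * rep(mids_y, each = nrow(n))) / N
  sxy <- sum(n * outer(mids_x - mx, mids_y - my)) / N
  sx <- sqrt(sum(n * (mids_x - mx)^2 * rep(1, ncol(n))) / N)
  sy <- sqrt(sum(t(n) * (mids_y - my)^2) / N)
  r0 <- max(min(sxy / (sx * sy), 0.95), -0.95)
  r1 <- max(min(r0 + 0.05 * sign(0.5 - r0), 0.95), -0.95)
  g0 <- score(r0); g1 <- score(r1)
  rho <- NA_real_
  for (it in 1:40) {
    if (!is.finite(g1) || g1 == g0) break
    r2 <- r1 - g1 * (r1 - r0) / (g1 - g0)
    if (!is.finite(r2) || abs(r2) > 0.9985) break
    r0 <- r1; g0 <- g1
    r1 <- r2; g1 <- score(r1)
    if (abs(r1 - r0) < 1e-9) { rho <- r1; break }
  }
  if (is.na(rho)) {
    # fall back to bounded likelihood maximization
    nll <- function(r) {
      p <- pmax(cell_probs(thresholds_x, thresholds_y, r), 1e-300)
      -sum(n * log(p))
    }
    opt <- optimize(nll, interval = c(-0.999, 0.999), tol = 1e-8)
    rho <- opt$minimum
    if (!is.finite(opt$objective)) rho <- 1   # trigger boundary signal
  }
  if (abs(rho) > 0.9985)
    stop(errorCondition("polychoric correlation at boundary",
                        class = "ordmi_nonconvergence"))
  rho
}

# score function pieces for one pair at fixed thresholds:
# d log pi_cell / d rho for every cell, and g = sum p_cell * dlogpi (the
# estimating equation whose root is rho-hat).
pair_dlogpi <- function(tx, ty, rho) {
  p <- pmax(cell_probs(tx, ty, rho), 1e-300)
  cell_probs_drho(tx, ty, rho) / p
}

#' First-stage polychoric summary for a two-group dataset
#'
#' Computes, per group, the univariate thresholds, the matrix of pairwise
#' polychoric correlations and the asymptotic covariance matrix of the
#' stacked first-stage statistics (thresholds in item order, then the lower
#' triangle of the correlation matrix in column-major pair order). The
#' covariance is the empirical covariance of per-person influence functions;
#' the influence of the threshold estimation on each correlation is accounted
#' for through the implicit-function derivative of the pairwise estimating
#' equation.
#'
#' @param data An `mi_data` object.
#' @param acov Compute the asymptotic covariance blocks? (Needed for DWLS
#'   weights and adjusted test statistics.)
#' @return Object of class `mi_polysum`: per group a list with `tau`
#'   (J x C-1), `rho` (J x J), `stat` (stacked statistic vector), `acov`
#'   (covariance matrix of `stat`) and `n`; plus `pairs` (2-column index
#'   matrix) and `n_categories`.
#' @export
polychoric_summary <- function(data, acov = TRUE) {
  stopifnot(inherits(data, "mi_data"))
  J <- ncol(data$responses)
  C <- data$n_categories
  pairs <- which(lower.tri(diag(J)), arr.ind = TRUE) # (row > col)
  groups <- lapply(levels(data$group), function(g) {
    X <- data$responses[data$group == g, , drop = FALSE]
    n <- nrow(X)
    tau <- matrix(0, J, C - 1L)
    for (j in seq_len(J)) {
      cnt <- tabulate(X[, j] + 1L, nbins = C)
      tau[j, ] <- univariate_thresholds(cnt)
    }
    rho <- diag(J)
    tabs <- vector("list", nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      tb <- table(factor(X[, j], levels = 0:(C - 1)),
                  factor(X[, i], levels = 0:(C - 1)))
      tabs[[k]] <- tb
      r <- polychoric_rho(tb, tau[j, ], tau[i, ])
      rho[i, j] <- rho[j, i] <- r
    }
    out <- list(tau = tau, rho = rho, n = n,
                stat = c(as.vector(t(tau)), rho[lower.tri(rho)]))
    if (acov)
      out$acov <- polychoric_acov(X, tau, rho, pairs, tabs, C)
    out
  })
  names(groups) <- levels(data$group)
  structure(
    list(groups = groups, pairs = pairs, n_categories = C, n_items = J),
    class = "mi_polysum"
  )
}

#' Asymptotic covariance of stacked polychoric statistics (one group)
#'
#' Influence-function (estimating-equation sandwich) estimate of the
#' covariance of the stacked (thresholds, lower-triangle correlations)
#' first-stage statistics, including the 1/N factor: the result estimates
#' `Cov(stat_hat)` directly.
#'
#' @param X Integer response matrix of one group (categories `0..C-1`).
#' @param tau J x (C-1) threshold estimates.
#' @param rho J x J polychoric correlation estimates.
#' @param pairs Optional lower-triangle pair index matrix.
#' @param tabs Optional list of pairwise tables matching `pairs`.
#' @param C Number of categories.
#' @return Symmetric covariance matrix of dimension
#'   `J*(C-1) + J*(J-1)/2`.
#' @export
polychoric_acov <- function(X, tau, rho, pairs = NULL, tabs = NULL,
                            C = max(X) + 1L) {
  n <- nrow(X); J <- ncol(X)
  if (is.null(pairs)) pairs <- which(lower.tri(diag(J)), arr.ind = TRUE)
  n_tau <- J * (C - 1L)
  m <- n_tau + nrow(pairs)
  Psi <- matrix(0, n, m)

  # thresholds: psi_i = (1{x <= c-1} - p_c) / dnorm(tau_c)
  cum <- vector("list", J)
  for (j in seq_len(J)) {
    p <- cumsum(tabulate(X[, j] + 1L, nbins = C))[seq_len(C - 1L)] / n
    cum[[j]] <- p
    for (cc in seq_len(C - 1L)) {
      col <- (j - 1L) * (C - 1L) + cc
      Psi[, col] <- ((X[, j] <= cc - 1L) - p[cc]) / dnorm(tau[j, cc])
    }
  }

  eps <- 1e-5
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]   # i > j
    ti <- tau[i, ]; tj <- tau[j, ]
    r <- rho[i, j]
    if (is.null(tabs)) {
      tb <- table(factor(X[, j], levels = 0:(C - 1)),
                  factor(X[, i], levels = 0:(C - 1)))
    } else tb <- tabs[[k]]
    ph <- tb / n
    # estimating equation g(rho, tau) = sum p_cell dlogpi_cell
    g_of <- function(r., tj., ti.) sum(ph * pair_dlogpi(tj., ti., r.))
    d_cell <- pair_dlogpi(tj, ti, r)                 # rows: item j, cols: item i
    g_rho <- (g_of(r + eps, tj, ti) - g_of(r - eps, tj, ti)) / (2 * eps)
    # dg/dtau for both items' thresholds
    g_tau_j <- vapply(seq_len(C - 1L), function(cc) {
      tp <- tj; tm <- tj
      tp[cc] <- tp[cc] + eps; tm[cc] <- tm[cc] - eps
      (g_of(r, tp, ti) - g_of(r, tm, ti)) / (2 * eps)
    }, numeric(1))
    g_tau_i <- vapply(seq_len(C - 1L), function(cc) {
      tp <- ti; tm <- ti
      tp[cc] <- tp[cc] + eps; tm[cc] <- tm[cc] - eps
      (g_of(r, tj, tp) - g_of(r, tj, tm)) / (2 * eps)
    }, numeric(1))
    cell_d <- d_cell[cbind(X[, j] + 1L, X[, i] + 1L)]
    tau_cols_j <- (j - 1L) * (C - 1L) + seq_len(C - 1L)
    tau_cols_i <- (i - 1L) * (C - 1L) + seq_len(C - 1L)
    corr_part <- Psi[, tau_cols_j, drop = FALSE] %*% g_tau_j +
      Psi[, tau_cols_i, drop = FALSE] %*% g_tau_i
    Psi[, n_tau + k] <- -(cell_d + as.vector(corr_part)) / g_rho
  }
  Psi <- sweep(Psi, 2, colMeans(Psi))
  crossprod(Psi) / n^2
}
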