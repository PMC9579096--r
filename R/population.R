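#' Population parameters of the simulation design
#'
#' Builds the two-group population of the unidimensional categorical factor
#' model used throughout the simulation study: standardized loadings
#' `lambda`, unique variances `sigma2 = 1 - lambda^2`, and per-item threshold
#' vectors on the latent-response scale. Both groups start identical (the
#' invariance baseline) with factor mean 0 and variance 1. Item 1 is the
#' anchor item: its parameters are never perturbed and every fitted model
#' constrains them equal across groups.
#'
#' The five-item parameter block is fixed (see [five_item_parameters()]); with
#' `n_items = 25` the block is repeated five times.
#'
#' @param n_items Number of items, 5 or 25.
#' @param n_categories Number of response categories per item, 3 or 5.
#' @return An object of class `mi_population`: a list with elements
#'   `reference` and `focal` (each with `factor_mean`, `factor_variance`,
#'   `loadings`, `unique_variances`, `thresholds` (J x C-1 matrix)),
#'   `n_categories`, and `anchor_item` (always 1).
#' @seealso [apply_dif()], [simulate_responses()]
#' @export
base_population <- function(n_items, n_categories) {
  if (!n_items %in% c(5L, 25L))
    stop("`n_items` must be 5 or 25", call. = FALSE)
  if (!n_categories %in% c(3L, 5L))
    stop("`n_categories` must be 3 or 5", call. = FALSE)
  pars <- five_item_parameters(n_categories)
  reps <- n_items / 5L
  lambda <- rep(pars$lambda, reps)
  sigma2 <- rep(pars$sigma2, reps)
  tau <- pars$tau[rep(seq_len(5L), reps), , drop = FALSE]
  rownames(tau) <- NULL
  grp <- list(
    factor_mean = 0,
    factor_variance = 1,
    loadings = lambda,
    unique_variances = sigma2,
    thresholds = tau
  )
  structure(
    list(
      reference = grp,
      focal = grp,
      n_categories = as.integer(n_categories),
      anchor_item = 1L
    ),
    class = "mi_population"
  )
}

#' Fixed five-item population parameter block
#'
#' The standardized loadings, unique variances and thresholds of the five-item
#' design. Thresholds of items 2 and 5 are the anchor quantile thresholds
#' shifted by +0.50, items 3 and 4 by -0.50.
#'
#' @param n_categories 3 or 5.
#' @return List with `lambda`, `sigma2`, `tau` (5 x C-1 matrix).
#' @export
five_item_parameters <- function(n_categories) {
  lambda <- c(.5, .7, .6, .4, .3)
  sigma2 <- c(.75, .51, .64, .84, .91)
  if (n_categories == 3L) {
    tau <- rbind(
      c(-0.38, 0.38),
      c(0.12, 0.88),
      c(-0.88, -0.12),
      c(-0.88, -0.12),
      c(0.12, 0.88)
    )
  } else if (n_categories == 5L) {
    tau <- rbind(
      c(-0.84, -0.25, 0.25, 0.84),
      c(-0.34, 0.25, 0.75, 1.34),
      c(-1.34, -0.75, -0.25, 0.34),
      c(-1.34, -0.75, -0.25, 0.34),
      c(-0.34, 0.25, 0.75, 1.34)
    )
  } else {
    stop("`n_categories` must be 3 or 5", call. = FALSE)
  }
  list(lambda = lambda, sigma2 = sigma2, tau = tau)
}

#' Empirical anchor thresholds from simulated continuous responses
#'
#' Diagnostic reconstruction of how the anchor-item thresholds arise: a large
#' continuous sample of the standardized item variable
#' `x = lambda * eta + eps` (unit total variance) is drawn and its empirical
#' tertiles (C = 3) or quintiles (C = 5) returned. Since the standardized
#' variable is standard normal, these converge to `qnorm(c(1:(C-1))/C)`.
#' Population thresholds of the non-anchor items are these values +- 0.50.
#'
#' @param n_categories 3 or 5.
#' @param loading Standardized loading of the anchor item (default .5).
#' @param n_draws Number of continuous draws (>= 10000 recommended).
#' @param seed Optional integer seed.
#' @return Numeric vector of C-1 strictly increasing thresholds.
#' @export
derive_anchor_thresholds <- function(n_categories, loading = 0.5,
                                     n_draws = 10000, seed = NULL) {
  if (!n_categories %in% c(3L, 5L))
    stop("`n_categories` must be 3 or 5", call. = FALSE)
  if (abs(loading) >= 1)
    stop("standardized `loading` must lie in (-1, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  eta <- stats::rnorm(n_draws)
  eps <- stats::rnorm(n_draws, sd = sqrt(1 - loading^2))
  x <- loading * eta + eps
  probs <- seq_len(n_categories - 1L) / n_categories
  unname(stats::quantile(x, probs = probs, type = 7))
}

#' Inject loading and/or threshold non-invariance into a population
#'
#' Perturbs the focal group of a two-group population. A fixed fraction of the
#' non-anchor items receives a loading change of `+-0.1` (small) or `+-0.2`
#' (large), and/or a shift of *all* thresholds of the item by `+-0.25` (small)
#' or `+-0.50` (large) standard deviations. Affected items are the first
#' eligible non-anchor items in index order. In `aligned` conditions every
#' affected item moves in the positive direction; in `misaligned` conditions
#' (only defined for 40%) the first half moves up and the second half down.
#' The reference group is never touched.
#'
#' @param pop An `mi_population`.
#' @param pct_loading,pct_threshold Percentage of items affected: 0, 20 or 40.
#' @param alignment `"aligned"` or `"misaligned"`.
#' @param magnitude `"small"` or `"large"`.
#' @return The perturbed `mi_population`.
#' @export
apply_dif <- function(pop, pct_loading = 0, pct_threshold = 0,
                      alignment = c("aligned", "misaligned"),
                      magnitude = c("small", "large")) {
  stopifnot(inherits(pop, "mi_population"))
  alignment <- match.arg(alignment)
  magnitude <- match.arg(magnitude)
  if (!pct_loading %in% c(0, 20, 40) || !pct_threshold %in% c(0, 20, 40))
    stop("DIF percentages must be 0, 20 or 40", call. = FALSE)
  if (alignment == "misaligned" &&
      any(c(pct_loading, pct_threshold) == 20))
    stop("misaligned changes are only defined for 40% of items", call. = FALSE)
  J <- length(pop$reference$loadings)
  d <- if (magnitude == "small") 0.1 else 0.2
  s <- if (magnitude == "small") 0.25 else 0.50

  signed_items <- function(pct) {
    n_aff <- round(pct / 100 * J)
    if (n_aff == 0L) return(NULL)
    items <- setdiff(seq_len(J), pop$anchor_item)[seq_len(n_aff)]
    sgn <- rep(1, n_aff)
    if (alignment == "misaligned")
      sgn[(n_aff %/% 2 + 1L):n_aff] <- -1
    list(items = items, sign = sgn)
  }

  foc <- pop$focal
  ld <- signed_items(pct_loading)
  if (!is.null(ld)) {
    foc$loadings[ld$items] <- foc$loadings[ld$items] + d * ld$sign
    bad <- foc$loadings[ld$items] <= 0 | foc$loadings[ld$items] >= 1
    if (any(bad))
      stop("perturbed standardized loading outside (0, 1)", call. = FALSE)
  }
  th <- signed_items(pct_threshold)
  if (!is.null(th)) {
    foc$thresholds[th$items, ] <- foc$thresholds[th$items, , drop = FALSE] +
      s * th$sign
  }
  pop$focal <- foc
  pop
}

#' Simulate two-group ordinal item responses
#'
#' Draws, per person, a factor score `eta ~ N(kappa, phi)` and latent
#' responses `x*_j = lambda_j * eta + eps_j` with `eps_j ~ N(0, sigma2_j)`,
#' then discretizes each latent response at the item's thresholds. Categories
#' are coded `0 .. C-1`. Group sizes are equal.
#'
#' @param pop An `mi_population`.
#' @param n_per_group Number of persons in each group.
#' @param seed Optional integer seed (same seed, same data).
#' @return An object of class `mi_data`: list with `responses` (integer
#'   matrix, 2N x J), `group` (factor with levels `r`, `f`) and
#'   `n_categories`.
#' @export
simulate_responses <- function(pop, n_per_group, seed = NULL) {
  stopifnot(inherits(pop, "mi_population"))
  if (!is.null(seed)) set.seed(seed)
  gen_group <- function(g, n) {
    J <- length(g$loadings)
    eta <- stats::rnorm(n, g$factor_mean, sqrt(g$factor_variance))
    xstar <- tcrossprod(eta, g$loadings) +
      matrix(stats::rnorm(n * J), n, J) %*% diag(sqrt(g$unique_variances), J)
    x <- matrix(0L, n, J)
    for (j in seq_len(J))
      x[, j] <- findInterval(xstar[, j], g$thresholds[j, ])
    x
  }
  xr <- gen_group(pop$reference, n_per_group)
  xf <- gen_group(pop$focal, n_per_group)
  structure(
    list(
      responses = rbind(xr, xf),
      group = factor(rep(c("r", "f"), each = n_per_group),
                     levels = c("r", "f")),
      n_categories = pop$n_categories
    ),
    class = "mi_data"
  )
}

#' Write / read an ordinal two-group dataset as CSV
#'
#' Plain one-header-line CSV with a `group` column (`r`/`f`) followed by
#' `item1..itemJ` integer columns.
#'
#' @param data An `mi_data` object.
#' @param path File path.
#' @param n_categories Number of categories; inferred from the data if `NULL`.
#' @return `read_mi_data` returns an `mi_data` object; `write_mi_data` its
#'   `path`, invisibly.
#' @export
write_mi_data <- function(data, path) {
  stopifnot(inherits(data, "mi_data"))
  df <- data.frame(group = as.character(data$group), data$responses)
  names(df) <- c("group", paste0("item", seq_len(ncol(data$responses))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mi_data
#' @export
read_mi_data <- function(path, n_categories = NULL) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "group")
    stop("first column must be `group`", call. = FALSE)
  resp <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(resp) <- "integer"
  dimnames(resp) <- NULL
  if (is.null(n_categories)) n_categories <- max(resp) + 1L
  if (any(resp < 0 | resp >= n_categories))
    stop("responses outside 0..C-1", call. = FALSE)
  structure(
    list(
      responses = resp,
      group = factor(df$group, levels = c("r", "f")),
      n_categories = as.integer(n_categories)
    ),
    class = "mi_data"
  )
}

#' Serialize a population specification to YAML
#'
#' @param pop An `mi_population`.
#' @param path File path; if `NULL` the YAML string is returned.
#' @export
write_mi_population <- function(pop, path = NULL) {
  stopifnot(inherits(pop, "mi_population"))
  as_plain <- function(g) {
    list(
      factor_mean = g$factor_mean,
      factor_variance = g$factor_variance,
      items = lapply(seq_along(g$loadings), function(j) {
        list(
          loading = g$loadings[j],
          unique_variance = g$unique_variances[j],
          thresholds = as.numeric(g$thresholds[j, ])
        )
      })
    )
  }
  obj <- list(
    n_categories = pop$n_categories,
    anchor_item = pop$anchor_item,
    reference = as_plain(pop$reference),
    focal = as_plain(pop$focal)
  )
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_mi_population
#' @export
read_mi_population <- function(path) {
  obj <- yaml::read_yaml(path)
  from_plain <- function(g) {
    list(
      factor_mean = g$factor_mean,
      factor_variance = g$factor_variance,
      loadings = vapply(g$items, `[[`, numeric(1), "loading"),
      unique_variances = vapply(g$items, `[[`, numeric(1), "unique_variance"),
      thresholds = do.call(rbind, lapply(g$items, function(it)
        as.numeric(it$thresholds)))
    )
  }
  structure(
    list(
      reference = from_plain(obj$reference),
      focal = from_plain(obj$focal),
      n_categories = as.integer(obj$n_categories),
      anchor_item = as.integer(obj$anchor_item)
    ),
    class = "mi_population"
  )
}

#' @export
print.mi_population <- function(x, ...) {
  J <- length(x$reference$loadings)
  cat(sprintf("Two-group ordinal population: %d items, %d categories\n",
              J, x$n_categories))
  dif <- which(x$reference$loadings != x$focal$loadings |
                 rowSums(x$reference$thresholds != x$focal$thresholds) > 0)
  if (length(dif)) {
    cat("non-invariant items:", paste(dif, collapse = ", "), "\n")
  } else {
    cat("groups are fully invariant\n")
  }
  invisible(x)
}

#' @export
print.mi_data <- function(x, ...) {
  cat(sprintf("mi_data: %d persons (%s), %d items, %d categories\n",
              nrow(x$responses),
              paste(table(x$group), collapse = " + "),
              ncol(x$responses), x$n_categories))
  invisible(x)
}
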