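# shared small fixtures; everything is generated in code under fixed seeds

tiny_data <- function(n = 250, J = 5, C = 3, seed = 1, pop = NULL) {
  if (is.null(pop)) pop <- base_population(J, C)
  simulate_responses(pop, n, seed = seed)
}

# population polychoric correlation implied by the generating factor model
pop_polychoric <- function(pop, group = "reference") {
  g <- pop[[group]]
  tot <- sqrt(g$loadings^2 * g$factor_variance + g$unique_variances)
  R <- (tcrossprod(g$loadings) * g$factor_variance) / tcrossprod(tot)
  diag(R) <- 1
  R
}

# brute-force grid-search ML polychoric correlation (independent oracle)
grid_rho <- function(tab, tx, ty, step = 1e-3) {
  grid <- seq(-0.99, 0.99, by = step)
  ll <- vapply(grid, function(r)
    sum(tab * log(pmax(ordmi:::cell_probs(tx, ty, r), 1e-300))), numeric(1))
  grid[which.max(ll)]
}
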