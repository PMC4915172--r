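# Independent oracles used by the tests. These never call the package's
# own estimation paths.

# Dense grid search maximizer of the two-parameter Weibull log-likelihood,
# refined around the argmax until the grid spacing is below `resolution`.
grid_weibull_mle <- function(t, grid_n = 200, resolution = 1e-5) {
  ll_grid <- function(alphas, betas) {
    n <- length(t); L1 <- sum(log(t))
    out <- matrix(NA_real_, length(alphas), length(betas))
    for (j in seq_along(betas)) {
      b <- betas[j]
      Sb <- sum(t^b)
      out[, j] <- n * log(b) - n * b * log(alphas) + (b - 1) * L1 -
        Sb / alphas^b
    }
    out
  }
  a_lo <- mean(t) / 5; a_hi <- mean(t) * 5
  b_lo <- 0.05; b_hi <- 10
  repeat {
    alphas <- seq(a_lo, a_hi, length.out = grid_n)
    betas <- seq(b_lo, b_hi, length.out = grid_n)
    ll <- ll_grid(alphas, betas)
    k <- arrayInd(which.max(ll), dim(ll))
    da <- alphas[2] - alphas[1]; db <- betas[2] - betas[1]
    if (da < resolution && db < resolution) {
      return(list(alpha = alphas[k[1]], beta = betas[k[2]],
                  loglik = ll[k[1], k[2]]))
    }
    a_lo <- max(alphas[k[1]] - 2 * da, 1e-8)
    a_hi <- alphas[k[1]] + 2 * da
    b_lo <- max(betas[k[2]] - 2 * db, 1e-8)
    b_hi <- betas[k[2]] + 2 * db
  }
}

# G-statistic (likelihood-ratio chi-square) for a 2x2 table, computed
# directly from observed and independence-expected counts.
g_statistic <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  2 * sum(O * log(O / E))
}
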