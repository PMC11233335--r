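# Independent oracles shared by the Bayes-factor tests.

# independent oracle: JZS paired BF via the effect-size parameterization
# (non-central t integrated over a Cauchy prior on delta), a different
# route from the package's g-integral
jzs_oracle <- function(x, r = sqrt(2) / 2) {
  n <- length(x)
  tstat <- mean(x) / (sd(x) / sqrt(n))
  num <- integrate(function(delta)
    suppressWarnings(dt(tstat, n - 1, ncp = delta * sqrt(n))) *
      dcauchy(delta, 0, r),
    -Inf, Inf, rel.tol = 1e-10, subdivisions = 1000L)$value
  num / dt(tstat, n - 1)
}

# independent BANOVA oracle: dense-matrix conditional marginal likelihood
# integrated over the g priors on an equal-probability quantile grid
banova_oracle_bf <- function(tab, effect = c("P", "D"), n_grid = 32,
                             rscale_fixed = 0.5, rscale_random = 1) {
  effect <- match.arg(effect)
  cells <- design_cells()
  S <- nrow(tab); N <- 4 * S
  y <- as.vector(t(tab[, cells$cell]))
  Z <- kronecker(diag(S), rep(1, 4))
  cvec <- if (effect == "P") rep(ifelse(cells$pleasantness == "pleasant",
                                        1, -1), S)
          else rep(ifelse(cells$difficulty == "difficult", 1, -1), S)
  logml <- function(X, gvec) {
    Sig <- diag(N) + X %*% (gvec * t(X))
    Si <- solve(Sig)
    one <- rep(1, N)
    q <- drop(t(y) %*% Si %*% y - (t(one) %*% Si %*% y)^2 /
                (t(one) %*% Si %*% one))
    -0.5 * determinant(Sig)$modulus - 0.5 * log(drop(t(one) %*% Si %*% one)) -
      (N - 1) / 2 * log(q)
  }
  # quantile-midpoint nodes of InverseGamma(1/2, r^2/2)
  ig_nodes <- function(r, k) {
    p <- (seq_len(k) - 0.5) / k
    r^2 / 2 / qgamma(1 - p, 1 / 2)
  }
  gs <- ig_nodes(rscale_random, n_grid)
  gf <- ig_nodes(rscale_fixed, n_grid)
  null_ml <- mean(vapply(gs, function(g1) exp(logml(Z, rep(g1, S))),
                         numeric(1)))
  alt_ml <- mean(vapply(gs, function(g1)
    mean(vapply(gf, function(g2)
      exp(logml(cbind(Z, cvec), c(rep(g1, S), g2))), numeric(1))),
    numeric(1)))
  alt_ml / null_ml
}

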