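# Independent reference implementations used to cross-check the package.
# These are deliberately naive (loops, textbook formulas) and share no
# code with the implementation under test.

# local convolutional forward pass by triple-nested loops
oracle_lcl_forward <- function(W, b, X, stride) {
  k <- ncol(W); nw <- nrow(W)
  out <- matrix(0, nrow(X), nw)
  for (r in seq_len(nrow(X))) {
    for (w in seq_len(nw)) {
      acc <- b[w]
      for (i in seq_len(k)) {
        acc <- acc + W[w, i] * X[r, (w - 1L) * stride + i]
      }
      out[r, w] <- max(acc, 0)
    }
  }
  out
}

# VanRaden GRM by an explicit double loop over individual pairs
oracle_grm <- function(M) {
  pfreq <- colMeans(M) / 2
  denom <- 2 * sum(pfreq * (1 - pfreq))
  Z <- sweep(M, 2, 2 * pfreq)
  G <- matrix(0, nrow(M), nrow(M))
  for (i in seq_len(nrow(M))) {
    for (j in seq_len(nrow(M))) {
      G[i, j] <- sum(Z[i, ] * Z[j, ]) / denom
    }
  }
  G
}

# RR-BLUP ridge solution equivalent to GBLUP under VanRaden scaling:
# marker effects u ~ N(0, sigma_g2 / c) with c = 2 sum p(1-p), so the
# ridge parameter is lambda * c; predictions are mu + Z u_hat.
oracle_rrblup_predict <- function(M, grm, fit, y_train, test_ids) {
  Z <- sweep(M, 2, 2 * grm$allele_freqs)
  Zt <- Z[fit$train_ids, , drop = FALSE]
  lam <- fit$lambda * grm$scaling_constant
  u <- solve(crossprod(Zt) + diag(lam, ncol(Zt)),
             crossprod(Zt, y_train - fit$mu))
  fit$mu + as.numeric(Z[test_ids, , drop = FALSE] %*% u)
}

# squared-correlation LD between two 0/1 haplotype columns
hap_r2 <- function(a, b) suppressWarnings(cor(a, b))^2
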