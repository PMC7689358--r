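test_that("VanRaden GRM matches hand and brute-force oracles", {
  # hand-evaluated toy: p = (.5, .5, .5), Z = M - 1, ZZ'/1.5
  M <- rbind(c(0, 1, 2), c(2, 1, 0))
  G <- vanraden_grm(M)
  expect_equal(G$matrix, matrix(c(4, -4, -4, 4) / 3, 2, 2))
  expect_equal(G$scaling_constant, 1.5)

  # duplicated genotype rows give identical GRM rows
  Md <- rbind(M, M[1, ])
  Gd <- vanraden_grm(Md)$matrix
  expect_equal(Gd[1, ], Gd[3, ])

  # 20 random instances against the double-loop oracle
  for (s in 1:20) {
    Mr <- random_dosage_matrix(15, 40, seed = s)
    expect_equal(vanraden_grm(Mr)$matrix, oracle_grm(Mr), tolerance = 1e-10)
  }
  expect_error(vanraden_grm(matrix(2L, 4, 3)), "monomorphic")
})

test_that("larger random GRM agrees with the brute-force oracle", {
  Mr <- random_dosage_matrix(50, 200, seed = 77)
  expect_lt(max(abs(vanraden_grm(Mr)$matrix - oracle_grm(Mr))), 1e-10)
})

test_that("GBLUP predictions coincide with RR-BLUP ridge on random instances", {
  for (s in 1:20) {
    n <- sample(30:80, 1)
    p <- sample(50:300, 1)
    M <- random_dosage_matrix(n, p, seed = 1000 + s)
    y <- withr::with_seed(2000 + s, {
      as.numeric(M %*% rnorm(p, 0, 0.1)) + rnorm(n)
    })
    train <- seq_len(round(0.8 * n))
    test <- setdiff(seq_len(n), train)
    grm <- vanraden_grm(M)
    fit <- gblup_fit(grm, y[train], train)
    pred_g <- predict_lm(fit, test)
    pred_r <- oracle_rrblup_predict(M, grm, fit, y[train], test)
    expect_equal(pred_g, pred_r, tolerance = 1e-6)
  }
})

test_that("GBLUP REML recovers the simulated heritability", {
  panel <- mid_panel()
  grm <- vanraden_grm(panel)
  h2_hat <- vapply(1:5, function(s) {
    ph <- simulate_trait(panel, 300, kind = "additive",
                         effect_distribution = "gaussian", h2 = 0.5,
                         seed = 500 + s)
    gblup_fit(grm, ph$phenotypes[, 1], seq_len(n_individuals(panel)))$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.05)
})

test_that("REML heritability is invariant to phenotype rescaling and location", {
  panel <- small_panel()
  grm <- vanraden_grm(panel)
  ph <- simulate_trait(panel, 50, h2 = 0.5, seed = 9)
  y <- ph$phenotypes[, 1]
  train <- 1:250
  f1 <- gblup_fit(grm, y[train], train)
  f10 <- gblup_fit(grm, 10 * y[train], train)
  expect_equal(f1$h2, f10$h2, tolerance = 1e-5)
  expect_equal(f1$lambda, f10$lambda, tolerance = 1e-4)
  # location equivariance: adding c to training phenotypes shifts
  # predictions by the same c
  fc <- gblup_fit(grm, y[train] + 5, train)
  expect_equal(predict_lm(fc, 251:300), predict_lm(f1, 251:300) + 5,
               tolerance = 1e-6)
})

test_that("full shrinkage limit predicts the grand mean", {
  # lambda -> infinity (sigma_g2 -> 0) shrinks every prediction to mu
  panel <- small_panel()
  grm <- vanraden_grm(panel)
  y <- withr::with_seed(10, rnorm(250))
  fit <- gblup_fit(grm, y, 1:250, lambda = 1e10)
  preds <- predict_lm(fit, 1:300)
  expect_lt(max(abs(preds - fit$mu)), 1e-6 * sd(y))
  expect_lt(abs(fit$mu - mean(y)), 1e-3 * sd(y))
})

test_that("EGBLUP kernel, nesting and variance attribution behave", {
  panel <- small_panel()
  grm <- vanraden_grm(panel)
  H <- grm$matrix * grm$matrix
  expect_equal(H, grm$matrix^2)  # Hadamard square by definition

  ph <- simulate_trait(panel, 50, h2 = 0.5, seed = 11)
  y <- ph$phenotypes[, 1]
  fit_g <- gblup_fit(grm, y[1:250], 1:250)
  fit_e0 <- egblup_fit(grm, y[1:250], 1:250, fix_sigma2 = TRUE)
  expect_equal(predict_lm(fit_e0, 251:300), predict_lm(fit_g, 251:300),
               tolerance = 1e-8)
  expect_identical(unname(fit_e0$variance_components["sigma2_g2"]), 0)

  # purely additive traits load the additive kernel
  ratios <- vapply(1:5, function(s) {
    phs <- simulate_trait(panel, 100, kind = "additive",
                          effect_distribution = "gaussian",
                          h2 = 0.5, seed = 600 + s)
    fit <- egblup_fit(grm, phs$phenotypes[1:250, 1], 1:250)
    vc <- fit$variance_components
    vc[["sigma2_g2"]] / max(vc[["sigma1_g2"]], 1e-12)
  }, numeric(1))
  expect_lt(mean(ratios), 0.5)
})

test_that("BayesA chains are deterministic, null on null data, and recover QTL", {
  panel <- mid_panel()
  # null phenotype: all posterior mean effects near zero
  y0 <- rep(0, 400)
  f0 <- bayesA_fit(panel, y0 + withr::with_seed(12, rnorm(400, 0, 1e-6)),
                   1:400, n_iter = 300, burn_in = 50, seed = 13)
  expect_lt(max(abs(f0$posterior_mean_effects)), 0.01)

  # determinism
  ph <- simulate_trait(panel, 10, kind = "additive",
                       effect_distribution = "equal", h2 = 0.8, seed = 14)
  y <- ph$phenotypes[, 1]
  f1 <- bayesA_fit(panel, y[1:1000], 1:1000, n_iter = 200, burn_in = 50, seed = 15)
  f2 <- bayesA_fit(panel, y[1:1000], 1:1000, n_iter = 200, burn_in = 50, seed = 15)
  expect_identical(f1$posterior_mean_effects, f2$posterior_mean_effects)

  # effect recovery on a 10-QTL trait
  f <- bayesA_fit(panel, y[1:1000], 1:1000, n_iter = 1000, burn_in = 200,
                  seed = 16)
  qtl <- attr(ph, "architecture")$additive$marker_index
  top <- order(abs(f$posterior_mean_effects), decreasing = TRUE)[1:10]
  expect_gte(length(intersect(top, qtl)), 5)  # top-10 enriched for true QTL
  # residual variance recovered within 20%
  true_se2 <- pop_var <- mean((ph$residuals[1:1000, 1] - mean(ph$residuals[1:1000, 1]))^2)
  expect_equal(f$posterior_mean_sigma_e2 / true_se2, 1, tolerance = 0.25)
})

test_that("predict_lm handles edge cases", {
  panel <- small_panel()
  grm <- vanraden_grm(panel)
  y <- withr::with_seed(17, rnorm(250))
  fit <- gblup_fit(grm, y, 1:250)
  expect_identical(predict_lm(fit, integer(0)), numeric(0))
  expect_equal(predict_lm(fit, 1:250), fit$mu + fit$blup[1:250])
  expect_error(predict_lm(fit, 999), "unknown ids")
  expect_error(gblup_fit(grm, c(1, NA, 3), 1:3), "finite|training")
})
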