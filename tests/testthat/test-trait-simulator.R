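test_that("architecture sampling respects kind, linkage and effect law", {
  panel <- small_panel()
  arch_add <- sample_architecture(panel, 10, kind = "additive",
                                  effect_distribution = "equal", seed = 1)
  expect_equal(nrow(arch_add$additive), 10L)
  expect_true(all(arch_add$additive$effect == arch_add$additive$effect[1]))
  expect_equal(anyDuplicated(arch_add$additive$marker_index), 0L)

  arch_epi <- sample_architecture(panel, 20, kind = "epistatic",
                                  effect_distribution = "gaussian", seed = 2)
  expect_length(arch_epi$epistatic, 20L)
  idx <- unlist(lapply(arch_epi$epistatic, function(q) c(q$a, q$b)))
  expect_equal(anyDuplicated(idx), 0L)  # disjoint pairs
  expect_true(all(vapply(arch_epi$epistatic,
                         function(q) length(q$table) == 9L, logical(1))))

  arch_lnk <- sample_architecture(panel, 15, kind = "linked_epistatic",
                                  max_link_distance = 5, seed = 3)
  d <- vapply(arch_lnk$epistatic, function(q) abs(q$a - q$b), numeric(1))
  expect_true(all(d <= 5))
  chrom <- panel$map$chromosome
  same_chrom <- vapply(arch_lnk$epistatic,
                       function(q) chrom[q$a] == chrom[q$b], logical(1))
  expect_true(all(same_chrom))

  expect_error(sample_architecture(panel, 5, kind = "linked_epistatic",
                                   max_link_distance = 0), "max_link_distance")
  expect_error(sample_architecture(panel, 10000, kind = "epistatic"), "exceed")
})

test_that("linked pairs never exceed the distance bound across many seeds", {
  map <- marker_map(500, 5)
  for (s in 1:10) {
    arch <- sample_architecture(map, 50, kind = "linked_epistatic",
                                max_link_distance = 5, seed = s)
    d <- vapply(arch$epistatic, function(q) abs(q$a - q$b), numeric(1))
    expect_lte(max(d), 5)
  }
})

test_that("genetic values match direct evaluation", {
  panel <- small_panel()
  # zero effects give zero genetic values
  arch0 <- sample_architecture(panel, 5, kind = "additive",
                               effect_distribution = "equal", seed = 4)
  arch0$additive$effect[] <- 0
  expect_equal(genetic_value(panel, arch0), rep(0, n_individuals(panel)))

  # single additive QTL with effect 1 reproduces its dosage column
  arch1 <- arch0
  arch1$additive <- data.frame(marker_index = 7L, effect = 1)
  expect_equal(genetic_value(panel, arch1),
               as.numeric(panel$dosages[, 7]))

  # linearity: doubling effects doubles g
  arch <- sample_architecture(panel, 10, kind = "additive",
                              effect_distribution = "gaussian", seed = 5)
  g1 <- genetic_value(panel, arch)
  arch$additive$effect <- 2 * arch$additive$effect
  expect_equal(genetic_value(panel, arch), 2 * g1)
})

test_that("epistatic lookup matches hand enumeration on a toy panel", {
  map <- marker_map(4, 1)
  dos <- rbind(c(0L, 2L, 1L, 0L),
               c(1L, 1L, 2L, 2L),
               c(2L, 0L, 0L, 1L))
  panel <- genotype_panel(dos, map)
  tbl <- matrix(1:9, 3, 3)  # table[da+1, db+1]
  arch <- structure(list(
    additive = data.frame(marker_index = integer(0), effect = numeric(0)),
    epistatic = list(list(a = 2L, b = 3L, table = tbl)),
    kind = "epistatic", linked = FALSE, max_link_distance = NA_integer_,
    effect_distribution = "equal"), class = "trait_architecture")
  # hand lookup: ind1 (2,1) -> tbl[3,2] = 6; ind2 (1,2) -> tbl[2,3] = 8;
  # ind3 (0,0) -> tbl[1,1] = 1
  expect_equal(genetic_value(panel, arch), c(6, 8, 1))
})

test_that("heritability scaling hits the target exactly in expectation", {
  g <- withr::with_seed(1, rnorm(10000))
  ph1 <- apply_heritability(g, h2 = 1, seed = 2)
  expect_equal(ph1$phenotypes[, 1], g)      # h2 = 1: no residual
  expect_equal(ph1$realized_h2, 1)

  ph5 <- apply_heritability(g, h2 = 0.5, seed = 3)
  # at h2 = 0.5 the residual variance equals Var(g) by construction
  expect_equal(var(ph5$residuals[, 1]) / var(g), 1, tolerance = 0.05)
  expect_equal(ph5$realized_h2, 0.5, tolerance = 0.02)

  expect_error(apply_heritability(rep(1, 10), 0.5), "constant")
  expect_error(apply_heritability(g, 0), "h2")
})

test_that("realized h2 and the sqrt(h2) correlation ceiling hold at n = 10,000", {
  g <- withr::with_seed(4, rnorm(10000))
  for (h2 in c(0.1, 0.3, 0.8)) {
    realized <- numeric(10)
    cor_gy <- numeric(10)
    for (s in 1:10) {
      ph <- apply_heritability(g, h2 = h2, seed = 100 + s)
      realized[s] <- ph$realized_h2
      cor_gy[s] <- cor(g, ph$phenotypes[, 1])
    }
    expect_equal(mean(realized), h2, tolerance = 0.02)
    expect_equal(mean(cor_gy), sqrt(h2), tolerance = 0.02)
  }
})

test_that("correlated traits achieve the target genetic correlation", {
  panel <- mid_panel()
  ph0 <- correlated_traits(panel, n_traits = 3, n_qtl = 500, rho = 0,
                           h2 = 0.5, seed = 6)
  cg0 <- cor(ph0$genetic_values)
  expect_true(all(abs(cg0[upper.tri(cg0)]) < 1e-8))

  ph8 <- correlated_traits(panel, n_traits = 3, n_qtl = 500, rho = 0.8,
                           h2 = 0.5, seed = 7)
  cg8 <- cor(ph8$genetic_values)
  expect_equal(mean(cg8[upper.tri(cg8)]), 0.8, tolerance = 1e-8)
  # phenotypic correlation is diluted by independent residuals
  cp8 <- cor(ph8$phenotypes)
  expect_lt(mean(cp8[upper.tri(cp8)]), 0.8)
  expect_error(correlated_traits(panel, 2, 10, rho = 1.2), "rho")
})

test_that("the effect-mixture reproduces the whitened Cholesky construction", {
  panel <- small_panel()
  ph <- correlated_traits(panel, n_traits = 2, n_qtl = 100, rho = 0.5,
                          h2 = 1, seed = 8)
  E <- attr(ph, "effects")
  qtl <- attr(ph, "qtl_index")
  # direct recomputation of the mixture from the same seed
  R <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  ref <- withr::with_seed(8L, {
    q <- sort(sample.int(n_markers(panel), 100))
    B <- matrix(rnorm(200), 100, 2)
    G0 <- panel$dosages[, q] %*% B
    W <- backsolve(chol(cov(G0)), diag(2))
    list(q = q, E = B %*% W %*% chol(R))
  })
  expect_equal(qtl, ref$q)
  expect_equal(E, ref$E)
  expect_equal(unname(ph$genetic_values[, 1]),
               unname(as.numeric(panel$dosages[, qtl] %*% E[, 1])))
})
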