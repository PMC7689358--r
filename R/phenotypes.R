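#' Add environmental noise to reach a target heritability
#'
#' Given genetic values g, draws i.i.d. Normal(0, sigma_e^2) residuals
#' with sigma_e^2 = Var(g) * (1 - h2) / h2, where Var is the realized
#' (population, divide-by-n) variance of g in the sample. This makes the
#' realized narrow-sense heritability Var(g) / Var(y) concentrate tightly
#' around the target. `h2 = 1` yields exactly zero residuals.
#'
#' @param genetic numeric n-vector of genetic values (non-constant unless
#'   h2 = 1 is meaningless and rejected).
#' @param h2 target heritability in (0, 1].
#' @param seed integer seed for the residual draw.
#' @return Object of class `phenotype_panel` (single trait): list with
#'   n x 1 matrices `genetic_values`, `residuals`, `phenotypes`, the
#'   vector `realized_h2` and the scalar `h2` requested.
#' @examples
#' g <- rnorm(500)
#' ph <- apply_heritability(g, h2 = 0.5, seed = 1)
#' ph$realized_h2
#' @export
apply_heritability <- function(genetic, h2, seed = 1L) {
  stopifnot(is.numeric(genetic), length(genetic) >= 2)
  if (!(h2 > 0 && h2 <= 1)) stop("`h2` must be in (0, 1]")
  vg <- pop_var(genetic)
  if (vg == 0) stop("genetic values are constant; heritability is undefined")
  sigma_e2 <- vg * (1 - h2) / h2
  resid <- if (h2 == 1) rep(0, length(genetic)) else {
    with_seed(seed, rnorm(length(genetic), 0, sqrt(sigma_e2)))
  }
  new_phenotype_panel(
    genetic_values = matrix(genetic, ncol = 1L),
    residuals = matrix(resid, ncol = 1L),
    h2 = h2
  )
}

#' @noRd
new_phenotype_panel <- function(genetic_values, residuals, h2) {
  phen <- genetic_values + residuals
  realized <- vapply(seq_len(ncol(phen)), function(t) {
    pop_var(genetic_values[, t]) / pop_var(phen[, t])
  }, numeric(1))
  if (is.null(colnames(phen))) {
    colnames(genetic_values) <- colnames(residuals) <- colnames(phen) <-
      sprintf("trait_%d", seq_len(ncol(phen)))
  }
  structure(list(genetic_values = genetic_values, residuals = residuals,
                 phenotypes = phen, realized_h2 = realized, h2 = h2),
            class = "phenotype_panel")
}

#' @export
print.phenotype_panel <- function(x, ...) {
  cat(sprintf("<phenotype_panel> %d individuals x %d trait(s); realized h2: %s\n",
              nrow(x$phenotypes), ncol(x$phenotypes),
              paste(sprintf("%.3f", x$realized_h2), collapse = ", ")))
  invisible(x)
}

#' Simulate a set of genetically correlated traits
#'
#' All traits share one set of `n_qtl` additive QTL positions; the
#' per-trait effect vectors are linear mixtures of i.i.d. standard-normal
#' effect vectors. The mixture first whitens the realized covariance of
#' the raw genetic values — in a related panel with LD the dosage
#' covariance has low effective rank, which would otherwise leave large
#' spurious correlations between nominally independent traits — and then
#' applies the Cholesky factor of the equicorrelation target (unit
#' diagonal, `rho` off-diagonal), so realized pairwise genetic
#' correlations match `rho` exactly in-sample. Residuals are drawn
#' independently per trait at the common heritability `h2`.
#'
#' @param panel a [genotype_panel()].
#' @param n_traits number of traits (>= 2), default 5.
#' @param n_qtl number of shared additive QTLs, default 1000.
#' @param rho target pairwise genetic correlation in [0, 1).
#' @param h2 heritability applied to every trait.
#' @param seed integer seed.
#' @return A multi-trait `phenotype_panel`; the attribute
#'   `"qtl_index"` records the shared QTL positions and `"effects"` the
#'   n_qtl x n_traits effect matrix.
#' @examples
#' panel <- simulate_genotype_panel(200, 400, 2, seed = 1)
#' ph <- correlated_traits(panel, n_traits = 2, n_qtl = 50, rho = 0.5,
#'                         h2 = 0.5, seed = 2)
#' cor(ph$genetic_values)
#' @export
correlated_traits <- function(panel, n_traits = 5L, n_qtl = 1000L, rho = 0.8,
                              h2 = 0.5, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_traits <- assert_count(n_traits, "n_traits", min = 2L)
  n_qtl <- assert_count(n_qtl, "n_qtl")
  if (!(rho >= 0 && rho < 1)) stop("`rho` must be in [0, 1)")
  p <- n_markers(panel)
  if (n_qtl > p) stop("n_qtl exceeds the number of markers")

  R <- matrix(rho, n_traits, n_traits); diag(R) <- 1
  L <- chol(R)  # upper triangular, R = t(L) %*% L

  res <- with_seed(seed, {
    qtl <- sort(sample.int(p, n_qtl))
    B <- matrix(rnorm(n_qtl * n_traits), n_qtl, n_traits)
    G0 <- panel$dosages[, qtl, drop = FALSE] %*% B
    # whiten the realized covariance, then impose the target correlation
    W <- backsolve(chol(stats::cov(G0)), diag(n_traits))
    E <- B %*% W %*% L
    G <- G0 %*% W %*% L
    dimnames(G) <- NULL
    resid <- matrix(0, nrow(G), n_traits)
    for (t in seq_len(n_traits)) {
      vg <- pop_var(G[, t])
      if (h2 < 1) resid[, t] <- rnorm(nrow(G), 0, sqrt(vg * (1 - h2) / h2))
    }
    list(qtl = qtl, E = E, G = G, resid = resid)
  })
  out <- new_phenotype_panel(res$G, res$resid, h2 = h2)
  attr(out, "qtl_index") <- res$qtl
  attr(out, "effects") <- res$E
  out
}

#' Simulate one trait on a panel
#'
#' Convenience wrapper: sample an architecture, compute genetic values and
#' apply heritability scaling.
#'
#' @inheritParams sample_architecture
#' @inheritParams apply_heritability
#' @param effect_distribution effect-size law; `NULL` (default) follows
#'   the benchmark convention of equal effects for additive traits and
#'   gaussian effects for epistatic ones.
#' @return A single-trait `phenotype_panel` with the architecture attached
#'   as attribute `"architecture"`.
#' @export
simulate_trait <- function(panel, n_qtl, kind = "additive",
                           effect_distribution = NULL,
                           max_link_distance = 5L, h2 = 0.5, seed = 1L) {
  if (is.null(effect_distribution)) {
    effect_distribution <- if (kind == "additive") "equal" else "gaussian"
  }
  arch <- sample_architecture(panel, n_qtl, kind = kind,
                              effect_distribution = effect_distribution,
                              max_link_distance = max_link_distance,
                              seed = seed)
  g <- genetic_value(panel, arch)
  out <- apply_heritability(g, h2 = h2, seed = derive_seed(seed, 2L))
  attr(out, "architecture") <- arch
  out
}
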