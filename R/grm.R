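#' VanRaden genomic relationship matrix
#'
#' Computes G = Z Z' / (2 * sum_j p_j (1 - p_j)) where Z = M - 2p is the
#' dosage matrix centered by twice the allele frequency of each marker
#' and the denominator is the expected heterozygosity summed over
#' markers. Allele frequencies are taken from the panel supplied (by
#' convention the full panel, training and prediction individuals
#' together, so a single G serves all cross-validation splits).
#' Monomorphic markers have a zero centered column and zero
#' heterozygosity, so they drop out of both numerator and denominator.
#'
#' @param panel a [genotype_panel()] or a bare n x p dosage matrix.
#' @return Object of class `grm`: list with `matrix` (n x n),
#'   `scaling_constant` (2 * sum p(1-p)) and `allele_freqs`.
#' @examples
#' M <- rbind(c(0, 1, 2), c(2, 1, 0))
#' vanraden_grm(M)$matrix
#' @export
vanraden_grm <- function(panel) {
  M <- if (inherits(panel, "genotype_panel")) panel$dosages else as.matrix(panel)
  pfreq <- colMeans(M) / 2
  denom <- 2 * sum(pfreq * (1 - pfreq))
  if (denom == 0) stop("all markers are monomorphic; the GRM is undefined")
  Z <- sweep(M, 2L, 2 * pfreq)
  G <- tcrossprod(Z) / denom
  structure(list(matrix = G, scaling_constant = denom, allele_freqs = pfreq),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d x %d VanRaden relationship matrix (2*sum p(1-p) = %.3f)\n",
              nrow(x$matrix), ncol(x$matrix), x$scaling_constant))
  invisible(x)
}
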