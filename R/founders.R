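#' Generate founder haplotypes with local linkage disequilibrium
#'
#' Founder haplotypes emulate the haplotype diversity of a breeding
#' population: each marker has a target allele frequency drawn uniformly
#' from `allele_freq_range`, and alleles along a chromosome follow a
#' first-order Markov chain — with probability `ld_strength` a haplotype
#' copies its allele state from the previous marker, otherwise it draws a
#' fresh Bernoulli(target frequency) allele. `ld_strength = 0` gives
#' linkage equilibrium; values near 1 give long identical-by-state runs,
#' i.e. strong local LD. Chromosomes are independent.
#'
#' Because every marginal frequency is a convex combination of target
#' frequencies inside `allele_freq_range`, realized frequencies stay
#' inside the requested interval up to sampling error.
#'
#' @param n_haplotypes number of haplotypes h (>= 2; use an even number if
#'   the set is later paired into diploid founders).
#' @param map a [marker_map()].
#' @param allele_freq_range length-2 interval inside (0, 1) for the
#'   per-marker target allele frequency. Default c(0.1, 0.9).
#' @param ld_strength copy probability in [0, 1); controls adjacent-marker
#'   correlation. Default 0.9 (array-like local LD).
#' @param seed integer seed; identical (arguments, seed) give bit-identical
#'   haplotypes.
#' @return An object of class `haplotype_set`: list with `haplotypes`
#'   (h x p 0/1 integer matrix) and `map`.
#' @examples
#' hs <- generate_founder_haplotypes(20, marker_map(50, 2), seed = 1)
#' dim(hs$haplotypes)
#' @export
generate_founder_haplotypes <- function(n_haplotypes, map,
                                        allele_freq_range = c(0.1, 0.9),
                                        ld_strength = 0.9,
                                        seed = 1L) {
  n_haplotypes <- assert_count(n_haplotypes, "n_haplotypes", min = 2L)
  validate_marker_map(map)
  p <- nrow(map)
  if (length(allele_freq_range) != 2L ||
      !(allele_freq_range[1] > 0 && allele_freq_range[2] < 1) ||
      allele_freq_range[1] > allele_freq_range[2]) {
    stop("`allele_freq_range` must be an interval [lo, hi] with 0 < lo <= hi < 1")
  }
  if (diff(allele_freq_range) == 0 &&
      (allele_freq_range[1] %in% c(0, 1))) {
    stop("degenerate allele frequency interval would give monomorphic markers")
  }
  stopifnot(ld_strength >= 0, ld_strength < 1)

  H <- with_seed(seed, {
    freqs <- runif(p, allele_freq_range[1], allele_freq_range[2])
    H <- matrix(0L, n_haplotypes, p)
    chrom <- map$chromosome
    for (j in seq_len(p)) {
      fresh <- rbinom(n_haplotypes, 1L, freqs[j])
      if (j > 1L && chrom[j] == chrom[j - 1L] && ld_strength > 0) {
        copy <- runif(n_haplotypes) < ld_strength
        H[, j] <- ifelse(copy, H[, j - 1L], fresh)
      } else {
        H[, j] <- fresh
      }
    }
    H
  })
  structure(list(haplotypes = H, map = map), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes x %d markers on %d chromosome(s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              length(unique(x$map$chromosome))))
  invisible(x)
}
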