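#' Random mating of founder haplotypes
#'
#' Pairs the founder haplotypes into diploid founder individuals
#' (consecutive haplotypes after a seeded shuffle) and produces offspring
#' by random mating: each offspring draws two founder parents uniformly
#' with replacement and receives one recombinant gamete from each. A
#' gamete is a crossover mosaic of the parent's two haplotypes; the
#' crossover count per chromosome is Poisson(genetic length in Morgans)
#' and crossover positions are uniform on the genetic map, so allele
#' frequencies are conserved in expectation while local LD of the founder
#' set is retained.
#'
#' @param founders a `haplotype_set` with an even number of haplotypes.
#' @param n_offspring number of offspring individuals to generate.
#' @param recombination_rate expected number of crossovers per chromosome
#'   (Morgans). `NULL` (default) uses each chromosome's map length; a
#'   scalar overrides it for all chromosomes; 0 disables recombination so
#'   every gamete is an intact parental haplotype.
#' @param seed integer seed; the whole pedigree is reproducible.
#' @return A [genotype_panel()] of `n_offspring` individuals.
#' @examples
#' hs <- generate_founder_haplotypes(40, marker_map(60, 2), seed = 1)
#' panel <- random_mating(hs, 100, seed = 2)
#' @export
random_mating <- function(founders, n_offspring, recombination_rate = NULL,
                          seed = 1L) {
  stopifnot(inherits(founders, "haplotype_set"))
  n_offspring <- assert_count(n_offspring, "n_offspring")
  H <- founders$haplotypes
  map <- founders$map
  h <- nrow(H)
  if (h %% 2L != 0L) stop("founders must contain an even number of haplotypes")
  n_founders <- h %/% 2L

  chroms <- unique(map$chromosome)
  chrom_cols <- lapply(chroms, function(ch) which(map$chromosome == ch))
  chrom_pos <- lapply(chrom_cols, function(cols) map$genetic_position[cols])
  chrom_len <- vapply(seq_along(chroms), function(i) {
    if (is.null(recombination_rate)) max(chrom_pos[[i]]) else recombination_rate
  }, numeric(1))
  p <- nrow(map)

  dos <- with_seed(seed, {
    perm <- sample.int(h)
    hap1 <- H[perm[seq(1L, h, by = 2L)], , drop = FALSE]  # founder maternal
    hap2 <- H[perm[seq(2L, h, by = 2L)], , drop = FALSE]  # founder paternal

    gamete <- function(parent) {
      g <- integer(p)
      for (i in seq_along(chroms)) {
        cols <- chrom_cols[[i]]
        pos <- chrom_pos[[i]]
        n_x <- rpois(1L, chrom_len[i])
        # segment parity: start haplotype random, switch at each crossover
        start <- rbinom(1L, 1L, 0.5)
        if (n_x == 0L) {
          use2 <- rep(start == 1L, length(cols))
        } else {
          xpos <- sort(runif(n_x, 0, max(pos)))
          seg <- findInterval(pos, xpos)
          use2 <- ((seg + start) %% 2L) == 1L
        }
        g[cols] <- ifelse(use2, hap2[parent, cols], hap1[parent, cols])
      }
      g
    }

    parents <- matrix(sample.int(n_founders, 2L * n_offspring, replace = TRUE),
                      ncol = 2L)
    out <- matrix(0L, n_offspring, p)
    for (o in seq_len(n_offspring)) {
      out[o, ] <- gamete(parents[o, 1L]) + gamete(parents[o, 2L])
    }
    out
  })
  genotype_panel(dos, map)
}

#' Simulate a breeding-population genotype panel
#'
#' Convenience wrapper chaining [generate_founder_haplotypes()] and
#' [random_mating()]. The default desk-scale configuration is 2,000
#' individuals x 3,000 markers on 10 chromosomes bred from 470 founder
#' haplotypes (235 diploid founders); pass `n_individuals = 10000,
#' n_markers = 34595` for the full-scale panel.
#'
#' @param n_individuals offspring panel size (default 2000).
#' @param n_markers marker count (default 3000).
#' @param n_chromosomes chromosomes (default 10).
#' @param n_founder_haplotypes founder haplotype count (default 470).
#' @param ld_strength,allele_freq_range passed to
#'   [generate_founder_haplotypes()].
#' @param seed master seed for founders and mating.
#' @return A [genotype_panel()].
#' @export
simulate_genotype_panel <- function(n_individuals = 2000L, n_markers = 3000L,
                                    n_chromosomes = 10L,
                                    n_founder_haplotypes = 470L,
                                    ld_strength = 0.9,
                                    allele_freq_range = c(0.1, 0.9),
                                    seed = 1L) {
  map <- marker_map(n_markers, n_chromosomes)
  founders <- generate_founder_haplotypes(
    n_founder_haplotypes, map,
    allele_freq_range = allele_freq_range,
    ld_strength = ld_strength, seed = seed
  )
  random_mating(founders, n_individuals, seed = derive_seed(seed, 1L))
}
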