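#' Sample a trait architecture
#'
#' Draws the QTL positions and effects defining a genetic-value function
#' on a marker panel. Three architecture kinds are supported:
#' `additive` (n_qtl single markers, each with a linear per-allele
#' effect), `epistatic` (n_qtl disjoint marker pairs, each with a full
#' 3 x 3 effect table over the nine dosage combinations 00, 01, ..., 22)
#' and `linked_epistatic` (epistatic pairs whose markers lie on the same
#' chromosome at most `max_link_distance` marker indices apart, emulating
#' local within-gene interactions).
#'
#' Effect sizes are either all equal to 1 (`equal`), i.i.d. standard
#' normal (`gaussian`), or gamma-distributed with shape 0.4 and random
#' sign (`gamma`). The absolute effect scale is immaterial once
#' heritability scaling is applied.
#'
#' @param panel a [genotype_panel()] or a bare [marker_map()] (positions
#'   only are needed).
#' @param n_qtl number of QTLs (markers for `additive`; pairs for the
#'   epistatic kinds).
#' @param kind one of `"additive"`, `"epistatic"`, `"linked_epistatic"`.
#' @param effect_distribution one of `"equal"`, `"gaussian"`, `"gamma"`.
#' @param max_link_distance maximum marker-index distance within a linked
#'   pair (default 5).
#' @param seed integer seed.
#' @return Object of class `trait_architecture`: list with `additive`
#'   (data.frame marker_index, effect), `epistatic` (list of pairs with
#'   `a`, `b`, `table`), `kind`, `linked`, `max_link_distance`,
#'   `effect_distribution`.
#' @examples
#' map <- marker_map(200, 2)
#' arch <- sample_architecture(map, 10, kind = "linked_epistatic", seed = 1)
#' max(vapply(arch$epistatic, function(q) abs(q$a - q$b), numeric(1)))
#' @export
sample_architecture <- function(panel, n_qtl,
                                kind = c("additive", "epistatic", "linked_epistatic"),
                                effect_distribution = c("equal", "gaussian", "gamma"),
                                max_link_distance = 5L,
                                seed = 1L) {
  kind <- match.arg(kind)
  effect_distribution <- match.arg(effect_distribution)
  n_qtl <- assert_count(n_qtl, "n_qtl")
  map <- if (inherits(panel, "genotype_panel")) panel$map else panel
  validate_marker_map(map)
  p <- nrow(map)
  linked <- kind == "linked_epistatic"
  if (linked) {
    max_link_distance <- assert_count(max_link_distance, "max_link_distance")
  }

  draw_effects <- function(n) {
    switch(effect_distribution,
      equal = rep(1, n),
      gaussian = rnorm(n),
      # heavy-tailed effects: shape 0.4, scale 1, random sign
      gamma = rgamma(n, shape = 0.4, scale = 1) * sample(c(-1, 1), n, replace = TRUE)
    )
  }

  out <- with_seed(seed, {
    if (kind == "additive") {
      if (n_qtl > p) stop("n_qtl exceeds the number of markers")
      idx <- sort(sample.int(p, n_qtl))
      list(additive = data.frame(marker_index = idx, effect = draw_effects(n_qtl)),
           epistatic = list())
    } else {
      if (2L * n_qtl > p) stop("n_qtl pairs exceed the number of markers")
      used <- logical(p)
      pairs <- vector("list", n_qtl)
      chrom <- map$chromosome
      for (q in seq_len(n_qtl)) {
        placed <- FALSE
        for (attempt in seq_len(1000L)) {
          a <- sample(which(!used), 1L)
          cand <- if (linked) {
            lo <- max(1L, a - max_link_distance)
            hi <- min(p, a + max_link_distance)
            nb <- lo:hi
            nb[nb != a & !used[nb] & chrom[nb] == chrom[a]]
          } else {
            which(!used & seq_len(p) != a)
          }
          if (length(cand) == 0L) next
          b <- if (length(cand) == 1L) cand else sample(cand, 1L)
          used[c(a, b)] <- TRUE
          pairs[[q]] <- list(a = a, b = b,
                             table = matrix(draw_effects(9L), 3L, 3L))
          placed <- TRUE
          break
        }
        if (!placed) stop("could not place all disjoint QTL pairs; reduce n_qtl")
      }
      list(additive = data.frame(marker_index = integer(0), effect = numeric(0)),
           epistatic = pairs)
    }
  })
  structure(
    c(out, list(kind = kind, linked = linked,
                max_link_distance = if (linked) max_link_distance else NA_integer_,
                effect_distribution = effect_distribution)),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  n <- if (x$kind == "additive") nrow(x$additive) else length(x$epistatic)
  cat(sprintf("<trait_architecture> %s, %d QTL%s, %s effects\n",
              x$kind, n, if (x$kind == "additive") "s" else " pairs",
              x$effect_distribution))
  invisible(x)
}

#' Genetic values of a panel under an architecture
#'
#' Deterministically evaluates the genetic-value function: the sum of
#' linear additive contributions (effect times dosage) plus, for each
#' epistatic pair, the table entry indexed by the individual's dosages at
#' the two markers.
#'
#' @param panel a [genotype_panel()].
#' @param arch a [sample_architecture()] result.
#' @return numeric n-vector of genetic values.
#' @export
genetic_value <- function(panel, arch) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(arch, "trait_architecture"))
  M <- panel$dosages
  p <- ncol(M)
  g <- numeric(nrow(M))
  if (nrow(arch$additive) > 0L) {
    idx <- arch$additive$marker_index
    if (any(idx < 1L | idx > p)) stop("additive QTL index out of range")
    g <- g + as.numeric(M[, idx, drop = FALSE] %*% arch$additive$effect)
  }
  for (q in arch$epistatic) {
    if (q$a < 1L || q$a > p || q$b < 1L || q$b > p) {
      stop("epistatic QTL index out of range")
    }
    g <- g + q$table[cbind(M[, q$a] + 1L, M[, q$b] + 1L)]
  }
  g
}
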