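#' Construct a genotype panel
#'
#' A genotype panel holds an n x p matrix of allele dosages in {0, 1, 2}
#' together with its marker map and sample identifiers. This is the
#' central genotype container consumed by the trait simulator, the linear
#' models and the neural networks.
#'
#' @param dosages n x p integer matrix with entries in {0, 1, 2}.
#' @param map a [marker_map()] with p rows.
#' @param sample_ids character vector of length n (default `ind_1..ind_n`).
#' @return Object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, map, sample_ids = NULL) {
  validate_marker_map(map)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (ncol(dosages) != nrow(map)) {
    stop("number of dosage columns must match the marker map")
  }
  if (anyNA(dosages) || !all(dosages %in% 0:2)) {
    stop("dosages must be complete with entries in {0, 1, 2}")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("ind_%d", seq_len(nrow(dosages)))
  stopifnot(length(sample_ids) == nrow(dosages))
  rownames(dosages) <- sample_ids
  colnames(dosages) <- map$marker_id
  structure(list(dosages = dosages, map = map, sample_ids = sample_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$map$chromosome))))
  invisible(x)
}

#' Number of individuals / markers in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_individuals <- function(panel) nrow(panel$dosages)

#' @rdname n_individuals
#' @export
n_markers <- function(panel) ncol(panel$dosages)

#' Per-marker allele frequencies of a panel
#' @param panel a `genotype_panel`.
#' @return numeric p-vector of alternate-allele frequencies (mean dosage / 2).
#' @export
allele_frequencies <- function(panel) colMeans(panel$dosages) / 2
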