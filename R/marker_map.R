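#' Build a marker map
#'
#' A marker map places `n_markers` biallelic SNPs on `n_chromosomes`
#' chromosomes, equidistantly spaced on a genetic map of
#' `chromosome_length` Morgans per chromosome. Markers are assigned to
#' chromosomes in contiguous, near-equal blocks and indexed 1..p in map
#' order.
#'
#' @param n_markers total number of markers (p >= 2).
#' @param n_chromosomes number of chromosomes (default 10, a maize-like
#'   karyotype).
#' @param chromosome_length genetic length of every chromosome in Morgans
#'   (default 1).
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `chromosome`, `genetic_position` (Morgans) and `index`.
#' @examples
#' map <- marker_map(100, n_chromosomes = 2)
#' table(map$chromosome)
#' @export
marker_map <- function(n_markers, n_chromosomes = 10L, chromosome_length = 1) {
  n_markers <- assert_count(n_markers, "n_markers", min = 2L)
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes")
  stopifnot(chromosome_length > 0, n_chromosomes <= n_markers)
  sizes <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1L)))
  chrom <- rep(seq_len(n_chromosomes), times = sizes)
  pos <- unlist(lapply(sizes, function(m) {
    # equidistant, strictly inside (0, L]
    chromosome_length * seq_len(m) / m
  }), use.names = FALSE)
  out <- data.frame(
    marker_id = sprintf("snp_%d", seq_len(n_markers)),
    chromosome = chrom,
    genetic_position = pos,
    index = seq_len(n_markers),
    stringsAsFactors = FALSE
  )
  class(out) <- c("marker_map", "data.frame")
  out
}

#' @noRd
validate_marker_map <- function(map) {
  stopifnot(
    is.data.frame(map),
    all(c("marker_id", "chromosome", "genetic_position", "index") %in% names(map)),
    identical(as.integer(map$index), seq_len(nrow(map))),
    all(map$genetic_position >= 0)
  )
  # positions non-decreasing within a chromosome
  for (ch in unique(map$chromosome)) {
    g <- map$genetic_position[map$chromosome == ch]
    if (is.unsorted(g)) stop("genetic positions must be non-decreasing within a chromosome")
  }
  invisible(map)
}
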