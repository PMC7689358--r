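#' Read a genotype panel from PLINK .raw or VCF
#'
#' PLINK `.raw` files (from `plink --recode A`) carry one allele-dosage
#' column per marker after the six pedigree columns
#' `FID IID PAT MAT SEX PHENOTYPE`. VCF genotypes are read through the
#' `vcfR` parser and GT fields are summed to dosages (e.g. `0/1` -> 1);
#' phasing separators `/` and `|` are both accepted. Missing calls are
#' imputed to the marker's rounded mean dosage and the imputation count
#' is reported via a message; markers missing in every sample are an
#' error.
#'
#' @param path file path.
#' @param format `"plink_raw"` or `"vcf"`; default guessed from the file
#'   extension.
#' @param map optional [marker_map()]; when absent a map is
#'   reconstructed (from a sibling `.map` file for PLINK, from
#'   CHROM/POS for VCF, genetic positions taken as position / 1e8,
#'   i.e. 1 cM per Mb).
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("auto", "plink_raw", "vcf"),
                           map = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink_raw"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "plink_raw") read_plink_raw(path, map) else read_vcf(path, map)
}

#' @noRd
read_plink_raw <- function(path, map = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  ped_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(ped_cols %in% names(dt)[1:6])) {
    stop("malformed PLINK .raw header: expected FID IID PAT MAT SEX PHENOTYPE")
  }
  geno <- as.matrix(dt[, -(1:6), drop = FALSE])
  # .raw marker columns are suffixed with the counted allele (snp_1_A)
  marker_ids <- sub("_[ACGT0-9]+$", "", colnames(geno))
  geno <- impute_missing(geno)
  if (is.null(map)) {
    map_path <- sub("\\.raw$", ".map", path)
    map <- if (file.exists(map_path)) read_plink_map(map_path) else {
      marker_map_from_ids(marker_ids)
    }
  }
  panel <- genotype_panel(geno, map, sample_ids = as.character(dt$IID))
  panel
}

#' @noRd
read_vcf <- function(path, map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  n_alleles <- lengths(alleles)
  if (any(n_alleles[!is.na(gt)] != 2L)) stop("only diploid GT fields are supported")
  dos <- matrix(vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_real_)
    sum(as.numeric(a))
  }, numeric(1)), nrow = nrow(gt))
  geno <- t(dos)  # samples x markers
  colnames(geno) <- rownames(gt)
  geno <- impute_missing(geno)
  if (is.null(map)) {
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    map <- data.frame(
      marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                         sprintf("snp_%d", seq_len(nrow(fix))), fix$ID),
      chromosome = as.integer(factor(fix$CHROM, levels = unique(fix$CHROM))),
      genetic_position = as.numeric(fix$POS) / 1e8,
      index = seq_len(nrow(fix)), stringsAsFactors = FALSE)
    class(map) <- c("marker_map", "data.frame")
  }
  genotype_panel(geno, map, sample_ids = colnames(gt))
}

#' @noRd
impute_missing <- function(geno) {
  miss <- is.na(geno)
  if (any(miss)) {
    all_missing <- colSums(!miss) == 0L
    if (any(all_missing)) {
      stop(sprintf("%d marker(s) are missing in every sample", sum(all_missing)))
    }
    means <- round(colMeans(geno, na.rm = TRUE))
    for (j in which(colSums(miss) > 0L)) geno[miss[, j], j] <- means[j]
    message(sprintf("imputed %d missing genotype call(s) to rounded mean dosage",
                    sum(miss)))
  }
  storage.mode(geno) <- "integer"
  geno
}

#' @noRd
marker_map_from_ids <- function(ids) {
  map <- data.frame(marker_id = ids, chromosome = 1L,
                    genetic_position = seq_along(ids) / length(ids),
                    index = seq_along(ids), stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Write a panel as PLINK .raw (+ .map)
#'
#' Emits the standard allele-dosage text format with header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one `<marker>_A` column
#' per marker, and a sibling 4-column PLINK `.map` file (chromosome,
#' marker id, genetic position in Morgans, integer map position).
#'
#' @param panel a [genotype_panel()].
#' @param path output `.raw` path.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  dt <- data.frame(FID = panel$sample_ids, IID = panel$sample_ids,
                   PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L)
  geno <- as.data.frame(panel$dosages)
  names(geno) <- paste0(panel$map$marker_id, "_A")
  data.table::fwrite(cbind(dt, geno), path, sep = " ", quote = FALSE)
  map_path <- sub("\\.raw$", ".map", path)
  if (map_path == path) map_path <- paste0(path, ".map")
  write_plink_map(panel$map, map_path)
  invisible(path)
}

#' @rdname write_plink_raw
#' @param map a [marker_map()].
#' @export
write_plink_map <- function(map, path) {
  validate_marker_map(map)
  data.table::fwrite(
    data.frame(map$chromosome, map$marker_id, map$genetic_position,
               round(map$genetic_position * 1e8)),
    path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a panel as VCF 4.2
#'
#' Dosages are emitted as unphased GT fields (0 -> `0/0`, 1 -> `0/1`,
#' 2 -> `1/1`) with placeholder REF/ALT alleles A/B and positions taken
#' from the genetic map (1 Morgan = 1e8 bp).
#'
#' @param panel a [genotype_panel()].
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=lcgp",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(n_markers(panel)), function(j) {
    paste(c(panel$map$chromosome[j],
            round(panel$map$genetic_position[j] * 1e8),
            panel$map$marker_id[j], "A", "B", ".", "PASS", ".", "GT",
            gt_code[panel$dosages[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @noRd
read_plink_map <- function(path) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE)
  map <- data.frame(marker_id = as.character(dt[[2]]),
                    chromosome = as.integer(dt[[1]]),
                    genetic_position = as.numeric(dt[[3]]),
                    index = seq_len(nrow(dt)), stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  map
}
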