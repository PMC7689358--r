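#' Write / read phenotype tables
#'
#' Phenotype CSVs carry a `sample_id` column followed by one column per
#' trait (`trait_1..trait_T`).
#'
#' @param phenotypes a `phenotype_panel` or phenotype matrix.
#' @param path output CSV path.
#' @param sample_ids ids to write (default `ind_1..n`).
#' @return `path` invisibly; `read_phenotypes` returns a numeric matrix
#'   with rownames set to the sample ids.
#' @export
write_phenotypes <- function(phenotypes, path, sample_ids = NULL) {
  Y <- if (inherits(phenotypes, "phenotype_panel")) phenotypes$phenotypes
       else as.matrix(phenotypes)
  if (is.null(sample_ids)) sample_ids <- sprintf("ind_%d", seq_len(nrow(Y)))
  df <- data.frame(sample_id = sample_ids, Y, check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype CSV must have a sample_id column")
  Y <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(Y) <- as.character(df$sample_id)
  Y
}

#' Serialize / restore a trait architecture as JSON
#'
#' The dump records QTL indices, effects and epistatic 3x3 tables so a
#' simulated trait is fully reproducible from its files.
#'
#' @param arch a `trait_architecture`.
#' @param path JSON path.
#' @return `path` invisibly; `read_architecture` returns the
#'   `trait_architecture`.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "trait_architecture"))
  obj <- list(
    kind = arch$kind,
    effect_distribution = arch$effect_distribution,
    linked = arch$linked,
    max_link_distance = arch$max_link_distance,
    additive = arch$additive,
    epistatic = lapply(arch$epistatic, function(q) {
      list(a = q$a, b = q$b, table = as.vector(q$table))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  additive <- as.data.frame(obj$additive)
  if (nrow(additive) == 0L) {
    additive <- data.frame(marker_index = integer(0), effect = numeric(0))
  }
  additive$marker_index <- as.integer(additive$marker_index)
  epistatic <- list()
  if (length(obj$epistatic)) {
    epi <- obj$epistatic
    if (is.data.frame(epi)) {
      epistatic <- lapply(seq_len(nrow(epi)), function(i) {
        list(a = as.integer(epi$a[i]), b = as.integer(epi$b[i]),
             table = matrix(unlist(epi$table[i]), 3L, 3L))
      })
    } else {
      epistatic <- lapply(epi, function(q) {
        list(a = as.integer(q$a), b = as.integer(q$b),
             table = matrix(unlist(q$table), 3L, 3L))
      })
    }
  }
  structure(list(additive = additive, epistatic = epistatic,
                 kind = obj$kind, linked = isTRUE(obj$linked),
                 max_link_distance = if (is.null(obj$max_link_distance) ||
                                         is.na(obj$max_link_distance)) NA_integer_
                                     else as.integer(obj$max_link_distance),
                 effect_distribution = obj$effect_distribution),
            class = "trait_architecture")
}

#' Read a benchmark run configuration (YAML or JSON)
#'
#' The configuration has four blocks — `simulation` (panel size, marker
#' count, chromosomes, LD), `trait` (architecture kind, n_qtl, h2,
#' correlations), `models` (list of model classes with settings) and
#' `evaluation` (repeats, fitting/validation sizes, master seed) — plus
#' an `output` directory. Missing required keys raise an error naming
#' the key. A persisted config together with its master seed reproduces
#' a run.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return named list with validated blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(
    simulation = list(n_individuals = 2000L, n_markers = 3000L,
                      n_chromosomes = 10L, n_founder_haplotypes = 470L,
                      ld_strength = 0.9),
    trait = list(kind = "additive", n_qtl = 1000L, h2 = 0.5,
                 effect_distribution = NULL, max_link_distance = 5L),
    models = list("GBLUP", "MLP", "CNN", "LCNN"),
    evaluation = list(n_repeats = 25L, train_fraction = 0.8,
                      validation_size = 0L, fitting_size = NULL,
                      max_epochs = 50L, mode = "early_stop_validation"),
    output = "lcgp_output",
    seed = 1L
  )
  for (block in c("simulation", "trait", "evaluation")) {
    if (!is.null(cfg[[block]])) {
      unknown <- setdiff(names(cfg[[block]]), names(defaults[[block]]))
      if (length(unknown)) {
        stop(sprintf("unknown key(s) in `%s` block: %s", block,
                     paste(unknown, collapse = ", ")))
      }
      defaults[[block]] <- modifyList(defaults[[block]], cfg[[block]])
    }
  }
  for (key in c("models", "output", "seed")) {
    if (!is.null(cfg[[key]])) defaults[[key]] <- cfg[[key]]
  }
  defaults
}
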