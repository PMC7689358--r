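#' Declare a linear-model predictor for the benchmark
#'
#' @param model_class `"GBLUP"`, `"EGBLUP"` or `"BayesA"`.
#' @param name optional label (defaults to the class).
#' @param n_iter,burn_in Gibbs settings for BayesA.
#' @return Object of class `lm_spec`.
#' @export
linear_model_spec <- function(model_class = c("GBLUP", "EGBLUP", "BayesA"),
                              name = NULL, n_iter = 5000L, burn_in = 1000L) {
  model_class <- match.arg(model_class)
  structure(list(model_class = model_class, name = name %||% model_class,
                 n_iter = n_iter, burn_in = burn_in),
            class = "lm_spec")
}

#' @export
print.lm_spec <- function(x, ...) {
  cat(sprintf("<lm_spec> %s\n", x$model_class))
  invisible(x)
}

#' The four baseline predictors of the benchmark
#'
#' GBLUP plus the three baseline network designs: MLP (two 64-node
#' FCLs), CNN (shared k = s = 10 convolution + two 64-node FCLs) and
#' LCNN (local k = s = 10 convolution + two 64-node FCLs).
#'
#' @param n_outputs trait count for the networks (default 1).
#' @return named list of model specs for [run_benchmark()].
#' @export
baseline_model_specs <- function(n_outputs = 1L) {
  list(
    GBLUP = linear_model_spec("GBLUP"),
    MLP = network_spec("MLP", n_outputs = n_outputs, name = "MLP"),
    CNN = network_spec("CNN", kernel_size = 10, stride = 10,
                       n_outputs = n_outputs, name = "CNN"),
    LCNN = network_spec("LCNN", kernel_size = 10, stride = 10,
                        n_outputs = n_outputs, name = "LCNN")
  )
}

#' Repeated cross-validation benchmark
#'
#' For each repeat a fresh random split is drawn and every model is
#' fitted on the identical fitting set and evaluated on the identical
#' test set, so models are directly comparable within repeat. Linear
#' models use all fitting individuals (training + validation); networks
#' train on the training set and use the validation set for epoch
#' selection (in early-stopping mode). The seed scheme — split seed
#' `master + r`, model-m seed `master + 10000 m + r` — makes the whole
#' benchmark reproducible, and deterministic models bit-reproducible.
#'
#' @param panel a [genotype_panel()].
#' @param phenotypes a `phenotype_panel` or an n x T phenotype matrix.
#' @param model_specs named list of [network_spec()] / [linear_model_spec()].
#' @param n_repeats repeats with fresh random splits (benchmark default
#'   25).
#' @param seed master seed.
#' @param fitting_size absolute fitting-set size (overrides
#'   `train_fraction`).
#' @param train_fraction default 0.8.
#' @param validation_size validation individuals within the fitting set.
#' @param train_cfg a [train_config()] template for the networks (its
#'   seed is re-derived per model and repeat).
#' @param h2 heritability used for standardized predictive ability;
#'   taken from the `phenotype_panel` when available.
#' @return Object of class `benchmark_result`: `results` (tidy
#'   data.frame: trait, model, repeat, train_size, predictive_ability,
#'   standardized_pa, selected_epoch, error) and `summary` (per
#'   trait/model mean with normal-theory 95% CI of the mean).
#' @export
run_benchmark <- function(panel, phenotypes, model_specs, n_repeats = 25L,
                          seed = 1L, fitting_size = NULL, train_fraction = 0.8,
                          validation_size = 0L, train_cfg = train_config(),
                          h2 = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), length(model_specs) >= 1L)
  n_repeats <- assert_count(n_repeats, "n_repeats")
  if (inherits(phenotypes, "phenotype_panel")) {
    if (is.null(h2)) h2 <- phenotypes$h2
    Y <- phenotypes$phenotypes
  } else {
    Y <- as.matrix(phenotypes)
  }
  n <- n_individuals(panel)
  stopifnot(nrow(Y) == n)
  n_traits <- ncol(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("trait_%d", seq_len(n_traits))
  if (is.null(names(model_specs))) {
    names(model_specs) <- vapply(model_specs, function(m) m$name, character(1))
  }
  needs_grm <- any(vapply(model_specs, function(m) {
    inherits(m, "lm_spec") && m$model_class %in% c("GBLUP", "EGBLUP")
  }, logical(1)))
  grm <- if (needs_grm) vanraden_grm(panel) else NULL

  rows <- list()
  for (r in seq_len(n_repeats)) {
    split <- make_split(n, train_fraction = train_fraction,
                        validation_size = validation_size,
                        seed = derive_seed(seed, 0L, r),
                        fitting_size = fitting_size)
    fit_ids <- sort(c(split$train, split$validation))
    for (m in seq_along(model_specs)) {
      spec <- model_specs[[m]]
      model_seed <- derive_seed(seed, m, r)
      cell <- tryCatch(
        fit_and_score(spec, panel, Y, grm, split, fit_ids, model_seed,
                      train_cfg),
        error = function(e) {
          data.frame(trait = colnames(Y), pa = NA_real_,
                     selected_epoch = NA_integer_,
                     error = conditionMessage(e))
        })
      rows[[length(rows) + 1L]] <- data.frame(
        trait = cell$trait, model = names(model_specs)[m], rep = r,
        train_size = length(fit_ids),
        predictive_ability = cell$pa,
        standardized_pa = if (!is.null(h2)) cell$pa / sqrt(h2) else NA_real_,
        selected_epoch = cell$selected_epoch,
        error = cell$error,
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, summary = summarize_benchmark(results)),
            class = "benchmark_result")
}

#' @noRd
fit_and_score <- function(spec, panel, Y, grm, split, fit_ids, model_seed,
                          train_cfg) {
  test <- split$test
  n_traits <- ncol(Y)
  if (inherits(spec, "lm_spec")) {
    pa <- vapply(seq_len(n_traits), function(t) {
      y_fit <- Y[fit_ids, t]
      fit <- switch(spec$model_class,
        GBLUP = gblup_fit(grm, y_fit, fit_ids),
        EGBLUP = egblup_fit(grm, y_fit, fit_ids),
        BayesA = bayesA_fit(panel, y_fit, fit_ids, n_iter = spec$n_iter,
                            burn_in = spec$burn_in, seed = model_seed))
      unname(predictive_ability(predict_lm(fit, test), Y[test, t])["pa"])
    }, numeric(1))
    data.frame(trait = colnames(Y), pa = pa, selected_epoch = NA_integer_,
               error = NA_character_)
  } else if (inherits(spec, "network_spec")) {
    cfg <- train_cfg
    cfg$seed <- model_seed
    X <- panel$dosages
    if (spec$n_outputs == n_traits) {
      trained <- train_network(
        spec, X[split$train, , drop = FALSE], Y[split$train, , drop = FALSE],
        X[split$validation, , drop = FALSE],
        Y[split$validation, , drop = FALSE], cfg)
      preds <- predict_network(trained, X[test, , drop = FALSE])
      pa <- vapply(seq_len(n_traits), function(t) {
        unname(predictive_ability(preds[, t], Y[test, t])["pa"])
      }, numeric(1))
      data.frame(trait = colnames(Y), pa = pa,
                 selected_epoch = trained$selected_epoch,
                 error = NA_character_)
    } else if (spec$n_outputs == 1L) {
      out <- lapply(seq_len(n_traits), function(t) {
        trained <- train_network(
          spec, X[split$train, , drop = FALSE], Y[split$train, t],
          X[split$validation, , drop = FALSE], Y[split$validation, t], cfg)
        preds <- predict_network(trained, X[test, , drop = FALSE])
        data.frame(trait = colnames(Y)[t],
                   pa = unname(predictive_ability(preds[, 1], Y[test, t])["pa"]),
                   selected_epoch = trained$selected_epoch,
                   error = NA_character_)
      })
      do.call(rbind, out)
    } else {
      stop("network n_outputs must be 1 or the number of traits")
    }
  } else {
    stop("unknown model spec class")
  }
}

#' Summarize a benchmark into per-cell means and 95% CIs
#'
#' @param results the tidy `results` data.frame of a `benchmark_result`.
#' @return data.frame with mean predictive ability and mean +/- 1.96 SE
#'   per (trait, model) cell.
#' @export
summarize_benchmark <- function(results) {
  cells <- split(results, interaction(results$trait, results$model, drop = TRUE))
  out <- lapply(cells, function(d) {
    pa <- d$predictive_ability[!is.na(d$predictive_ability)]
    se <- if (length(pa) > 1L) sd(pa) / sqrt(length(pa)) else NA_real_
    data.frame(trait = d$trait[1], model = d$model[1],
               n_repeats = length(pa), mean_pa = mean(pa),
               ci_lower = mean(pa) - 1.96 * se,
               ci_upper = mean(pa) + 1.96 * se,
               mean_standardized_pa = mean(d$standardized_pa[!is.na(d$predictive_ability)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$trait, out$model), ]
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
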