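#' Random train/validation/test split
#'
#' Splits `n` individuals uniformly at random into a fitting set of
#' `round(train_fraction * n)` individuals — itself divided into a
#' training set and a validation set of `validation_size` — and a test
#' set holding everyone else. With the benchmark defaults (n = 10,000,
#' 80% fitting, validation 1,000) the sizes are 7,000 / 1,000 / 2,000.
#'
#' @param n panel size.
#' @param train_fraction fraction of individuals used for model fitting
#'   (training + validation; default 0.8).
#' @param validation_size individuals reserved for epoch selection
#'   (default 0: two-way split).
#' @param seed integer seed; identical seeds give identical splits.
#' @param fitting_size absolute fitting-set size; overrides
#'   `train_fraction` when given.
#' @return Object of class `split_plan`: integer index vectors `train`,
#'   `validation`, `test` (mutually disjoint, covering 1..n) and `seed`.
#' @examples
#' sp <- make_split(10000, validation_size = 1000, seed = 1)
#' lengths(sp[c("train", "validation", "test")])
#' @export
make_split <- function(n, train_fraction = 0.8, validation_size = 0L,
                       seed = 1L, fitting_size = NULL) {
  n <- assert_count(n, "n", min = 3L)
  validation_size <- assert_count(validation_size, "validation_size", min = 0L)
  n_fit <- if (!is.null(fitting_size)) {
    assert_count(fitting_size, "fitting_size")
  } else {
    round(train_fraction * n)
  }
  if (n_fit > n) stop("fitting set larger than the panel")
  if (validation_size >= n_fit) stop("validation set must be smaller than the fitting set")
  idx <- with_seed(seed, sample.int(n))
  fit_ids <- idx[seq_len(n_fit)]
  structure(list(
    train = sort(fit_ids[seq_len(n_fit - validation_size)]),
    validation = if (validation_size > 0L) {
      sort(fit_ids[(n_fit - validation_size + 1L):n_fit])
    } else integer(0),
    test = sort(idx[-seq_len(n_fit)]),
    seed = as.integer(seed)
  ), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / validation %d / test %d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test), x$seed))
  invisible(x)
}

#' Training-size sweep grid
#'
#' The benchmark protocol varies the number of individuals used for
#' model fitting over (100, 250, 500, 1,000, 2,000, 3,000, 4,000, 6,000,
#' 8,000) with paired validation sizes (20, 50, 100, 200, 300, 400, 500,
#' 750, 1,000) — the validation share is larger for small panels. All
#' remaining individuals form the test set. Sizes exceeding `n - 1` are
#' dropped with a warning so the grid can be used on desk-scale panels.
#'
#' @param n panel size.
#' @param seed seed passed to each [make_split()].
#' @return list of `split_plan`s, one per (fitting, validation) pair,
#'   with attribute `"grid"` holding the size table.
#' @export
training_size_grid <- function(n, seed = 1L) {
  fit_sizes <- c(100L, 250L, 500L, 1000L, 2000L, 3000L, 4000L, 6000L, 8000L)
  val_sizes <- c(20L, 50L, 100L, 200L, 300L, 400L, 500L, 750L, 1000L)
  keep <- fit_sizes < n
  if (!all(keep)) {
    warning(sprintf("panel of %d individuals: grid truncated to fitting sizes <= %d",
                    n, max(fit_sizes[keep])))
  }
  fit_sizes <- fit_sizes[keep]; val_sizes <- val_sizes[keep]
  plans <- lapply(seq_along(fit_sizes), function(i) {
    make_split(n, validation_size = val_sizes[i], seed = seed,
               fitting_size = fit_sizes[i])
  })
  attr(plans, "grid") <- data.frame(fitting_size = fit_sizes,
                                    validation_size = val_sizes)
  plans
}

#' Predictive ability
#'
#' Pearson correlation between predictions and observed phenotypes of
#' individuals not used in training. When a heritability is supplied the
#' standardized predictive ability r / sqrt(h2) is also returned —
#' sqrt(h2) being the highest predictive ability theoretically
#' achievable for a trait of heritability h2 (see [pa_ceiling()]).
#' Zero-variance inputs make the correlation undefined; `NA` is returned
#' with a warning, never a silent 0.
#'
#' @param predictions,phenotypes equal-length numeric vectors (>= 3).
#' @param h2 optional heritability for standardization.
#' @return named numeric: `pa`, and `standardized_pa` if `h2` is given.
#' @export
predictive_ability <- function(predictions, phenotypes, h2 = NULL) {
  stopifnot(length(predictions) == length(phenotypes),
            length(predictions) >= 3L)
  if (sd(predictions) == 0 || sd(phenotypes) == 0) {
    warning("zero-variance input: predictive ability is undefined")
    r <- NA_real_
  } else {
    r <- cor(predictions, phenotypes)
  }
  out <- c(pa = r)
  if (!is.null(h2)) out <- c(out, standardized_pa = r / sqrt(h2))
  out
}

#' Theoretical predictive-ability ceiling
#'
#' The correlation between any predictor of the genetic value and the
#' phenotype is bounded by sqrt(h2): at h2 = 0.5 the ceiling is 0.707.
#'
#' @param h2 heritability in (0, 1].
#' @return sqrt(h2).
#' @export
pa_ceiling <- function(h2) {
  stopifnot(all(h2 > 0), all(h2 <= 1))
  sqrt(h2)
}
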