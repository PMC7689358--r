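#' Declare a network architecture
#'
#' Describes one predictor from the three ANN classes benchmarked for
#' genomic prediction:
#' * `MLP` — fully connected layers only;
#' * `CNN` — one shared-weight convolutional layer (CL) in front of the
#'   fully connected layers, no pooling;
#' * `LCNN` — one *local* convolutional layer (LCL): the same windowing
#'   as a CL but with an independent filter per genomic window, so a
#'   region-specific effect can be learned for every stretch of markers.
#'
#' The baseline designs use kernel size and stride 10, one filter (CNN),
#' two hidden layers of 64 nodes, ReLU activations, a linear output and
#' dropout 0.3 after each hidden layer.
#'
#' @param model_class `"MLP"`, `"CNN"` or `"LCNN"`.
#' @param kernel_size window width k in markers (conv classes; default 10).
#' @param stride window step s in markers (default = `kernel_size`, i.e.
#'   non-overlapping windows).
#' @param n_filters number of shared filters for the CNN (default 1).
#' @param fcl_nodes integer vector of fully-connected hidden-layer widths
#'   (default `c(64, 64)`).
#' @param n_outputs number of traits predicted jointly (default 1).
#' @param dropout_rate dropout probability after each hidden layer
#'   (default 0.3).
#' @param name optional label used in benchmark reports.
#' @return Object of class `network_spec`.
#' @examples
#' baseline_lcnn <- network_spec("LCNN")
#' count_parameters(baseline_lcnn, p = 34595)
#' @export
network_spec <- function(model_class = c("MLP", "CNN", "LCNN"),
                         kernel_size = 10L, stride = kernel_size,
                         n_filters = 1L, fcl_nodes = c(64L, 64L),
                         n_outputs = 1L, dropout_rate = 0.3,
                         name = NULL) {
  model_class <- match.arg(model_class)
  n_outputs <- assert_count(n_outputs, "n_outputs")
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  if (length(fcl_nodes) > 0) {
    fcl_nodes <- vapply(fcl_nodes, assert_count, integer(1), name = "fcl_nodes")
  } else {
    fcl_nodes <- integer(0)
  }
  conv <- NULL
  if (model_class != "MLP") {
    kernel_size <- assert_count(kernel_size, "kernel_size")
    stride <- assert_count(stride, "stride")
    n_filters <- assert_count(n_filters, "n_filters")
    conv <- list(kernel_size = kernel_size, stride = stride,
                 n_filters = if (model_class == "CNN") n_filters else 1L)
  }
  structure(list(model_class = model_class, conv = conv,
                 fcl_nodes = fcl_nodes, n_outputs = n_outputs,
                 dropout_rate = dropout_rate,
                 name = name %||% model_class),
            class = "network_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.network_spec <- function(x, ...) {
  conv <- if (is.null(x$conv)) "no conv layer" else {
    sprintf("%s k=%d s=%d%s",
            if (x$model_class == "CNN") "CL" else "LCL",
            x$conv$kernel_size, x$conv$stride,
            if (x$model_class == "CNN") sprintf(" filters=%d", x$conv$n_filters) else "")
  }
  cat(sprintf("<network_spec> %s: %s; FCLs [%s]; %d output(s); dropout %.2f\n",
              x$model_class, conv, paste(x$fcl_nodes, collapse = ", "),
              x$n_outputs, x$dropout_rate))
  invisible(x)
}

#' Number of windows of a (local) convolutional layer
#'
#' `floor((p - k) / s) + 1` full windows; trailing markers that do not
#' fill a window are dropped ("valid" convolution).
#'
#' @param p input markers, @param kernel_size window width,
#' @param stride window step.
#' @return integer window count.
#' @export
n_windows <- function(p, kernel_size, stride = kernel_size) {
  if (p < kernel_size) stop("p must be at least the kernel size")
  as.integer((p - kernel_size) %/% stride + 1L)
}

#' Per-layer weight and intercept counts
#'
#' @param spec a [network_spec()].
#' @param p number of input markers.
#' @return data.frame with columns `layer`, `weights`, `intercepts`.
#' @export
layer_parameter_counts <- function(spec, p) {
  stopifnot(inherits(spec, "network_spec"))
  p <- assert_count(p, "p")
  rows <- list()
  width <- p
  if (!is.null(spec$conv)) {
    k <- spec$conv$kernel_size; s <- spec$conv$stride
    nw <- n_windows(p, k, s)
    if (spec$model_class == "CNN") {
      f <- spec$conv$n_filters
      rows[[length(rows) + 1L]] <- data.frame(
        layer = "conv", weights = f * k, intercepts = f)
      width <- nw * f
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = "local_conv", weights = nw * k, intercepts = nw)
      width <- nw
    }
  }
  widths <- c(spec$fcl_nodes, spec$n_outputs)
  for (i in seq_along(widths)) {
    nm <- if (i == length(widths)) "output" else sprintf("fcl_%d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = nm, weights = width * widths[i], intercepts = widths[i])
    width <- widths[i]
  }
  do.call(rbind, rows)
}

#' Count trainable parameters of a network
#'
#' Exact count of trainable weights plus intercepts for every layer of
#' the architecture: a shared CL filter of kernel k with one filter
#' counts k + 1; an LCL counts n_windows * (k + 1); a fully connected
#' layer from `in` to `out` nodes counts `in * out + out`.
#'
#' @inheritParams layer_parameter_counts
#' @return integer total parameter count.
#' @examples
#' count_parameters(network_spec("CNN", kernel_size = 10), p = 1000)  # conv part is 11
#' @export
count_parameters <- function(spec, p) {
  counts <- layer_parameter_counts(spec, p)
  as.integer(sum(counts$weights) + sum(counts$intercepts))
}
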