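# Layer machinery for the MLP/CNN/LCNN predictors. The local
# convolutional layer is evaluated with a gather-and-group-sum scheme:
# the input columns of all windows are gathered side by side, multiplied
# elementwise by the flattened window weights, and summed per window
# through a fixed sparse 0/1 matrix. This keeps the whole forward and
# backward pass in BLAS/sparse products with no per-window loops.

# column indices that place the k markers of each window side by side
#' @noRd
window_gather_index <- function(p, k, s) {
  nw <- n_windows(p, k, s)
  as.vector(vapply(seq_len(nw), function(w) (w - 1L) * s + seq_len(k),
                   integer(k)))
}

# sparse (nw*k x nw) group-sum operator: column w sums its k gathered inputs
#' @noRd
window_sum_matrix <- function(nw, k) {
  Matrix::sparseMatrix(i = seq_len(nw * k), j = rep(seq_len(nw), each = k),
                       x = 1, dims = c(nw * k, nw))
}

#' Construct a local convolutional layer
#'
#' An LCL applies an independent affine filter to each window of
#' `kernel_size` adjacent markers, stepping by `stride`; window w reads
#' input positions (w-1)*stride + 1 ... (w-1)*stride + kernel_size and
#' trailing markers beyond the last full window are dropped. Unlike a
#' shared convolution, the weights of different windows are free
#' parameters.
#'
#' @param weights n_windows x kernel_size matrix (row w = filter of
#'   window w).
#' @param intercepts numeric n_windows-vector.
#' @param stride window step (default = kernel size).
#' @return Object of class `local_conv_layer`.
#' @export
local_conv_layer <- function(weights, intercepts, stride = ncol(weights)) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == length(intercepts), stride >= 1)
  structure(list(kernel_size = ncol(weights), stride = as.integer(stride),
                 n_windows = nrow(weights), weights = weights,
                 intercepts = as.numeric(intercepts)),
            class = "local_conv_layer")
}

#' Forward pass of a local convolutional layer
#'
#' Computes `out[b, w] = ReLU(sum_i W[w, i] * x[b, (w-1)*s + i] + b[w])`
#' for every row of the input batch.
#'
#' @param layer a [local_conv_layer()].
#' @param inputs batch x p numeric matrix; p must cover
#'   `(n_windows - 1) * stride + kernel_size` positions.
#' @return batch x n_windows matrix of ReLU activations.
#' @examples
#' lay <- local_conv_layer(matrix(1, 2, 3), c(0, 0), stride = 3)
#' lcl_forward(lay, matrix(1:12, 2, 6))
#' @export
lcl_forward <- function(layer, inputs) {
  stopifnot(inherits(layer, "local_conv_layer"))
  inputs <- as.matrix(inputs)
  k <- layer$kernel_size; s <- layer$stride; nw <- layer$n_windows
  need <- (nw - 1L) * s + k
  if (ncol(inputs) < need) stop("input has fewer markers than the layer's windows cover")
  idx <- window_gather_index(ncol(inputs), k, s)[seq_len(nw * k)]
  Xg <- inputs[, idx, drop = FALSE]
  B <- nrow(Xg)
  wflat <- as.vector(t(layer$weights))
  A <- as.matrix(Xg %*% window_filter_matrix(wflat, nw, k)) +
    rep(layer$intercepts, each = B)
  pmax(A, 0)
}

# sparse (nw*k x nw) matrix whose column w holds the window-w weights
#' @noRd
window_filter_matrix <- function(wflat, nw, k) {
  Matrix::sparseMatrix(i = seq_len(nw * k), j = rep(seq_len(nw), each = k),
                       x = wflat, dims = c(nw * k, nw))
}

#' Build an initialized network
#'
#' Assembles the layer stack input -> (optional conv/local conv) ->
#' fully connected hidden layers -> linear output(s), with ReLU on all
#' hidden layers and dropout applied (at training time) after each
#' hidden layer. Weights use a seeded Glorot-style uniform
#' initialization on (-sqrt(6/(fan_in+fan_out)), +sqrt(...)); intercepts
#' start at zero.
#'
#' @param spec a [network_spec()].
#' @param p number of input markers.
#' @param seed integer seed; identical seeds give identical initial
#'   weights.
#' @return Object of class `network`: the spec, `p` and the layer list.
#' @export
build_network <- function(spec, p, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  p <- assert_count(p, "p", min = 2L)
  glorot <- function(n, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    runif(n, -lim, lim)
  }
  layers <- with_seed(seed, {
    out <- list()
    width <- p
    if (!is.null(spec$conv)) {
      k <- spec$conv$kernel_size; s <- spec$conv$stride
      if (p < k) stop("kernel size exceeds the number of markers")
      nw <- n_windows(p, k, s)
      idx <- window_gather_index(p, k, s)
      if (spec$model_class == "LCNN") {
        out[[length(out) + 1L]] <- list(
          type = "lcl", activation = "relu", k = k, s = s, nw = nw,
          idx = idx, Sm = window_sum_matrix(nw, k),
          W = matrix(glorot(nw * k, k, 1), nw, k, byrow = TRUE),
          b = numeric(nw))
        width <- nw
      } else {
        f <- spec$conv$n_filters
        out[[length(out) + 1L]] <- list(
          type = "conv", activation = "relu", k = k, s = s, nw = nw,
          n_filters = f, idx = idx, Sm = window_sum_matrix(nw, k),
          W = matrix(glorot(f * k, k, 1), f, k, byrow = TRUE),
          b = numeric(f))
        width <- nw * f
      }
    }
    widths <- c(spec$fcl_nodes, spec$n_outputs)
    for (i in seq_along(widths)) {
      w_out <- widths[i]
      last <- i == length(widths)
      out[[length(out) + 1L]] <- list(
        type = "dense", activation = if (last) "linear" else "relu",
        W = matrix(glorot(width * w_out, width, w_out), width, w_out),
        b = numeric(w_out))
      width <- w_out
    }
    out
  })
  structure(list(spec = spec, p = p, layers = layers, seed = seed),
            class = "network")
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network> %s on p = %d inputs, %d trainable parameters\n",
              x$spec$model_class, x$p, count_parameters(x$spec, x$p)))
  invisible(x)
}

# full forward pass; training = TRUE draws dropout masks from the
# current RNG stream and records everything needed for backprop
#' @noRd
net_forward <- function(net, X, training = FALSE) {
  H <- X
  B <- nrow(X)
  rate <- net$spec$dropout_rate
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    lay <- net$layers[[li]]
    cache <- list(input = H)
    if (lay$type == "lcl") {
      Xg <- if (identical(lay$idx, seq_len(ncol(H)))) H else H[, lay$idx, drop = FALSE]
      wflat <- as.vector(t(lay$W))
      A <- as.matrix(Xg %*% window_filter_matrix(wflat, lay$nw, lay$k)) +
        rep(lay$b, each = B)
      cache$Xg <- Xg
    } else if (lay$type == "conv") {
      Xg <- if (identical(lay$idx, seq_len(ncol(H)))) H else H[, lay$idx, drop = FALSE]
      A <- matrix(0, B, lay$nw * lay$n_filters)
      for (f in seq_len(lay$n_filters)) {
        Ff <- window_filter_matrix(rep(lay$W[f, ], lay$nw), lay$nw, lay$k)
        A[, (f - 1L) * lay$nw + seq_len(lay$nw)] <-
          as.matrix(Xg %*% Ff) + lay$b[f]
      }
      cache$Xg <- Xg
    } else {
      A <- H %*% lay$W + rep(lay$b, each = B)
    }
    if (lay$activation == "relu") {
      mask <- A > 0
      H <- A * mask
      cache$relu_mask <- mask
      if (training && rate > 0) {
        keep <- matrix(runif(length(H)) >= rate, nrow(H), ncol(H)) / (1 - rate)
        H <- H * keep
        cache$drop_mask <- keep
      }
    } else {
      H <- A
    }
    caches[[li]] <- cache
  }
  list(out = H, caches = caches)
}

# backward pass for the mean-squared-error loss; returns per-layer
# gradients aligned with net$layers
#' @noRd
net_backward <- function(net, caches, d_out) {
  grads <- vector("list", length(net$layers))
  dH <- d_out
  for (li in rev(seq_along(net$layers))) {
    lay <- net$layers[[li]]
    cache <- caches[[li]]
    if (!is.null(cache$drop_mask)) dH <- dH * cache$drop_mask
    if (lay$activation == "relu") dH <- dH * cache$relu_mask
    if (lay$type == "dense") {
      grads[[li]] <- list(W = crossprod(cache$input, dH), b = colSums(dH))
      if (li > 1L) dH <- tcrossprod(dH, lay$W)
    } else if (lay$type == "lcl") {
      Dg <- as.matrix(dH %*% Matrix::t(lay$Sm))
      dwflat <- colSums(cache$Xg * Dg)
      grads[[li]] <- list(W = t(matrix(dwflat, lay$k, lay$nw)), b = colSums(dH))
      # conv layers sit first; no input gradient needed
    } else {
      dW <- matrix(0, lay$n_filters, lay$k)
      db <- numeric(lay$n_filters)
      for (f in seq_len(lay$n_filters)) {
        dHf <- dH[, (f - 1L) * lay$nw + seq_len(lay$nw), drop = FALSE]
        Dg <- as.matrix(dHf %*% Matrix::t(lay$Sm))
        dW[f, ] <- rowSums(matrix(colSums(cache$Xg * Dg), lay$k, lay$nw))
        db[f] <- sum(dHf)
      }
      grads[[li]] <- list(W = dW, b = db)
    }
  }
  grads
}
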