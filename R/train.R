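#' Training configuration
#'
#' @param mode `"early_stop_validation"` (default): train for up to
#'   `max_epochs` epochs, evaluate the validation predictive ability
#'   (Pearson correlation of predictions and validation phenotypes,
#'   averaged over traits) after every epoch, and keep the weights of the
#'   best epoch (earliest on ties). `"fixed_epochs"`: run exactly
#'   `max_epochs` epochs and ignore any validation data.
#' @param max_epochs epoch budget; default 50 for early stopping and 25
#'   for the fixed-epoch protocol.
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed integer seed driving shuffling, dropout and (via
#'   [build_network()]) initialization.
#' @return Object of class `train_config`.
#' @export
train_config <- function(mode = c("early_stop_validation", "fixed_epochs"),
                         max_epochs = NULL, batch_size = 64L,
                         learning_rate = 1e-3, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(max_epochs)) {
    max_epochs <- if (mode == "early_stop_validation") 50L else 25L
  }
  structure(list(mode = mode,
                 max_epochs = assert_count(max_epochs, "max_epochs"),
                 batch_size = assert_count(batch_size, "batch_size"),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a network by Adam on the mean squared error
#'
#' Phenotypes are centered per trait on the training set (the training
#' means are stored and added back by [predict_network()]); genotype
#' dosages enter raw as 0/1/2. The loss is the unweighted sum of
#' per-trait mean squared errors, minimized with the Adam optimizer. In
#' early-stopping mode the validation predictive ability is computed
#' after every epoch (dropout disabled) and the weights of the best
#' epoch are restored; in fixed-epoch mode validation inputs are ignored
#' entirely.
#'
#' @param net a [build_network()] result (or a [network_spec()], in which
#'   case the network is built with the config seed).
#' @param X_train n x p dosage matrix; @param y_train n-vector or n x T
#'   matrix of phenotypes.
#' @param X_val,y_val validation data (required in early-stopping mode,
#'   ignored in fixed-epoch mode).
#' @param config a [train_config()].
#' @return Object of class `trained_network`: the trained `network`,
#'   `y_means`, `selected_epoch`, `history` (per-epoch data.frame with
#'   `epoch`, `train_loss`, `val_pa`) and `config`.
#' @export
train_network <- function(net, X_train, y_train, X_val = NULL, y_val = NULL,
                          config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  X_train <- as.matrix(X_train); storage.mode(X_train) <- "double"
  Y <- as.matrix(y_train)
  if (inherits(net, "network_spec")) net <- build_network(net, ncol(X_train), config$seed)
  stopifnot(inherits(net, "network"))
  if (ncol(X_train) != net$p) stop("X_train column count does not match the network")
  if (nrow(Y) != nrow(X_train)) stop("X_train and y_train sizes differ")
  if (ncol(Y) != net$spec$n_outputs) {
    stop(sprintf("network predicts %d trait(s) but y_train has %d column(s)",
                 net$spec$n_outputs, ncol(Y)))
  }
  early <- config$mode == "early_stop_validation"
  if (early) {
    if (is.null(X_val) || is.null(y_val) || NROW(y_val) == 0L) {
      stop("early-stopping mode requires a non-empty validation set")
    }
    X_val <- as.matrix(X_val); storage.mode(X_val) <- "double"
    Yv <- as.matrix(y_val)
    stopifnot(ncol(X_val) == net$p, nrow(Yv) == nrow(X_val),
              ncol(Yv) == ncol(Y))
  }

  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_means)
  n <- nrow(X_train)
  n_batches <- ceiling(n / config$batch_size)

  state <- with_seed(config$seed, {
    opt <- adam_init(net$layers, config$learning_rate)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_pa = numeric(0))
    best <- list(pa = -Inf, epoch = NA_integer_, layers = NULL)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      for (bi in seq_len(n_batches)) {
        rows <- ord[((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, n)]
        Xb <- X_train[rows, , drop = FALSE]
        Yb <- Yc[rows, , drop = FALSE]
        fw <- net_forward(net, Xb, training = TRUE)
        err <- fw$out - Yb
        loss <- sum(colMeans(err^2))
        if (!is.finite(loss)) {
          stop(sprintf("training loss became non-finite at epoch %d", epoch))
        }
        epoch_loss <- epoch_loss + loss * length(rows)
        grads <- net_backward(net, fw$caches, 2 * err / nrow(Xb))
        upd <- adam_step(net$layers, grads, opt)
        net$layers <- upd$layers
        opt <- upd$opt
      }
      val_pa <- NA_real_
      if (early) {
        pred_v <- net_forward(net, X_val, training = FALSE)$out
        pa <- vapply(seq_len(ncol(Yv)), function(t) {
          if (sd(pred_v[, t]) == 0 || sd(Yv[, t]) == 0) return(NA_real_)
          cor(pred_v[, t], Yv[, t])
        }, numeric(1))
        val_pa <- mean(pa, na.rm = FALSE)
        if (is.na(val_pa)) val_pa <- -Inf  # degenerate epoch, never selected
        if (val_pa > best$pa) {
          best <- list(pa = val_pa, epoch = epoch,
                       layers = lapply(net$layers, function(l) l[c("W", "b")]))
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = epoch_loss / n,
        val_pa = if (early) val_pa else NA_real_))
    }
    list(net = net, history = history, best = best)
  })

  net <- state$net
  selected <- config$max_epochs
  if (early && !is.null(state$best$layers)) {
    for (li in seq_along(net$layers)) {
      net$layers[[li]]$W <- state$best$layers[[li]]$W
      net$layers[[li]]$b <- state$best$layers[[li]]$b
    }
    selected <- state$best$epoch
  }
  structure(list(network = net, spec = net$spec, y_means = y_means,
                 selected_epoch = selected, history = state$history,
                 config = config),
            class = "trained_network")
}

#' Predict phenotypes with a trained network
#'
#' Dropout is disabled; predictions are deterministic and returned on
#' the phenotype scale (training means added back), one column per
#' trait.
#'
#' @param trained a [train_network()] result.
#' @param X dosage matrix with the training marker count.
#' @return n x n_outputs numeric matrix.
#' @export
predict_network <- function(trained, X) {
  stopifnot(inherits(trained, "trained_network"))
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (ncol(X) != trained$network$p) {
    stop(sprintf("X has %d markers but the network was trained on %d",
                 ncol(X), trained$network$p))
  }
  out <- net_forward(trained$network, X, training = FALSE)$out
  sweep(out, 2L, trained$y_means, `+`)
}

#' @export
print.trained_network <- function(x, ...) {
  cat(sprintf("<trained_network> %s, selected epoch %d of %d (%s mode)\n",
              x$spec$model_class, x$selected_epoch, x$config$max_epochs,
              x$config$mode))
  invisible(x)
}

# Adam optimizer state and update -------------------------------------------

#' @noRd
adam_init <- function(layers, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)))
}

#' @noRd
adam_step <- function(layers, grads, opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (li in seq_along(layers)) {
    for (par in c("W", "b")) {
      g <- grads[[li]][[par]]
      m <- opt$beta1 * opt$m[[li]][[par]] + (1 - opt$beta1) * g
      v <- opt$beta2 * opt$v[[li]][[par]] + (1 - opt$beta2) * g^2
      opt$m[[li]][[par]] <- m
      opt$v[[li]][[par]] <- v
      layers[[li]][[par]] <- layers[[li]][[par]] -
        opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    }
  }
  list(layers = layers, opt = opt)
}
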