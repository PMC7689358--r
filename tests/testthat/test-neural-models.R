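test_that("window counting follows the valid-convolution rule", {
  expect_equal(n_windows(34595, 10, 10), 3459L)
  expect_equal(n_windows(30, 3, 3), 10L)
  expect_equal(n_windows(31, 3, 3), 10L)   # trailing marker dropped
  expect_equal(n_windows(30, 10, 5), 5L)   # overlapping windows
  expect_error(n_windows(5, 10), "kernel")
})

test_that("parameter accounting reproduces the published arithmetic", {
  # shared filter of kernel 10: 10 weights + 1 intercept
  cnn1 <- network_spec("CNN", kernel_size = 10, fcl_nodes = integer(0),
                       n_outputs = 1)
  conv_row <- layer_parameter_counts(cnn1, 1000)[1, ]
  expect_equal(conv_row$weights + conv_row$intercepts, 11)

  # baseline MLP at p = 34,595: 2.2 million parameters
  mlp <- network_spec("MLP")
  expect_equal(count_parameters(mlp, 34595), 34595L * 64L + 64L + 64L * 64L + 64L + 64L + 1L)
  expect_equal(round(count_parameters(mlp, 34595) / 1e6, 1), 2.2)

  # weights-only ratio first-FCL / LCL is exactly 64 when k = s divides p
  p <- 34590L  # divisible by 10
  fcl_weights <- layer_parameter_counts(mlp, p)$weights[1]
  lcl_weights <- layer_parameter_counts(network_spec("LCNN"), p)$weights[1]
  expect_equal(fcl_weights / lcl_weights, 64)

  # baseline ordering at p = 34,595: MLP > LCNN > CNN > 0
  n_mlp <- count_parameters(network_spec("MLP"), 34595)
  n_cnn <- count_parameters(network_spec("CNN"), 34595)
  n_lcnn <- count_parameters(network_spec("LCNN"), 34595)
  expect_true(n_mlp > n_lcnn && n_lcnn > n_cnn && n_cnn > 0)
  # reconstructible exact totals with one filter and per-window intercepts
  expect_equal(n_cnn, 225676L)
  expect_equal(n_lcnn, 263714L)
})

test_that("LCL forward matches the triple-loop oracle and the CL tie", {
  for (s in 1:20) {
    cfg <- withr::with_seed(s, {
      k <- sample(2:5, 1)
      stride <- sample(1:k, 1)
      p <- sample(20:40, 1)
      nw <- n_windows(p, k, stride)
      list(k = k, stride = stride, p = p, nw = nw,
           W = matrix(rnorm(nw * k), nw, k),
           b = rnorm(nw),
           X = matrix(sample(0:2, 6 * p, replace = TRUE), 6, p))
    })
    lay <- local_conv_layer(cfg$W, cfg$b, stride = cfg$stride)
    expect_equal(lcl_forward(lay, cfg$X),
                 oracle_lcl_forward(cfg$W, cfg$b, cfg$X, cfg$stride),
                 tolerance = 1e-10)
  }

  # zero weights and intercepts give identically zero output
  lay0 <- local_conv_layer(matrix(0, 4, 3), rep(0, 4))
  expect_true(all(lcl_forward(lay0, matrix(1:24, 2, 12)) == 0))

  # weight-tied LCL reproduces a shared-filter convolution exactly
  filt <- c(0.5, -1, 2)
  W_tied <- matrix(filt, 4, 3, byrow = TRUE)
  X <- matrix(rnorm(36), 3, 12)
  tied <- lcl_forward(local_conv_layer(W_tied, rep(0.1, 4)), X)
  shared <- oracle_lcl_forward(W_tied, rep(0.1, 4), X, 3)
  expect_equal(tied, shared)
})

test_that("network building is seed-deterministic and spec-faithful", {
  spec <- network_spec("LCNN")
  n1 <- build_network(spec, 200, seed = 5)
  n2 <- build_network(spec, 200, seed = 5)
  expect_identical(n1$layers, n2$layers)
  n3 <- build_network(spec, 200, seed = 6)
  expect_false(identical(n1$layers[[1]]$W, n3$layers[[1]]$W))

  # baseline LCNN: one LCL (k = s = 10) then two 64-node FCLs and output
  types <- vapply(n1$layers, `[[`, character(1), "type")
  expect_equal(types, c("lcl", "dense", "dense", "dense"))
  expect_equal(n1$layers[[1]]$k, 10L)
  expect_equal(n1$layers[[1]]$s, 10L)
  expect_equal(dim(n1$layers[[2]]$W), c(20L, 64L))

  # multi-trait head
  multi <- build_network(network_spec("LCNN", n_outputs = 5), 200, seed = 7)
  expect_equal(ncol(multi$layers[[4]]$W), 5L)
})

test_that("training fits a separable linear signal and logs history", {
  X <- random_dosage_matrix(1000, 50, seed = 20)
  y <- as.numeric(X[, 17])  # noiseless single-marker trait
  tn <- train_network(network_spec("MLP", dropout_rate = 0),
                      X, y, config = train_config("fixed_epochs",
                                                  max_epochs = 25, seed = 21))
  preds <- predict_network(tn, X)
  expect_gt(cor(preds[, 1], y), 0.95)
  expect_lt(tn$history$train_loss[25], tn$history$train_loss[1])
})

test_that("early stopping selects the best epoch and restores its weights", {
  panel <- small_panel()
  ph <- simulate_trait(panel, 10, h2 = 0.8, seed = 22)
  X <- panel$dosages; y <- ph$phenotypes[, 1]
  tn <- train_network(network_spec("LCNN"), X[1:200, ], y[1:200],
                      X[201:260, ], y[201:260],
                      train_config(max_epochs = 15, seed = 23))
  expect_lte(tn$selected_epoch, 15L)
  best <- max(tn$history$val_pa)
  expect_equal(tn$history$val_pa[tn$selected_epoch], best)
  # first maximum on ties / the restored model reproduces the best epoch PA
  expect_equal(which.max(tn$history$val_pa), tn$selected_epoch)
  pred_v <- predict_network(tn, X[201:260, ])
  expect_equal(unname(cor(pred_v[, 1], y[201:260])), best, tolerance = 1e-10)
  expect_error(train_network(network_spec("MLP"), X[1:100, ], y[1:100],
                             config = train_config()),
               "validation")
})

test_that("fixed-epoch mode ignores validation data entirely", {
  X <- random_dosage_matrix(200, 40, seed = 24)
  y <- withr::with_seed(25, rnorm(200))
  cfg <- train_config("fixed_epochs", max_epochs = 5, seed = 26)
  t1 <- train_network(network_spec("MLP"), X[1:150, ], y[1:150], config = cfg)
  t2 <- train_network(network_spec("MLP"), X[1:150, ], y[1:150],
                      X[151:200, ], y[151:200], cfg)
  expect_identical(lapply(t1$network$layers, `[[`, "W"),
                   lapply(t2$network$layers, `[[`, "W"))
  expect_equal(t1$selected_epoch, 5L)
})

test_that("prediction is deterministic, shape-correct and validated", {
  X <- random_dosage_matrix(120, 60, seed = 27)
  Y <- withr::with_seed(28, matrix(rnorm(240), 120, 2))
  tn <- train_network(network_spec("CNN", kernel_size = 5, n_outputs = 2),
                      X, Y, config = train_config("fixed_epochs",
                                                  max_epochs = 3, seed = 29))
  p1 <- predict_network(tn, X)
  p2 <- predict_network(tn, X)
  expect_identical(p1, p2)           # dropout off at inference
  expect_equal(dim(p1), c(120L, 2L)) # one column per trait
  # constant input rows give constant outputs
  Xc <- matrix(1L, 5, 60)
  expect_equal(max(apply(predict_network(tn, Xc), 2, sd)), 0)
  expect_error(predict_network(tn, X[, 1:10]), "markers")
})
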