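test_that("architecture specs enforce their invariants", {
  expect_error(deep2d_spec(grid_shape = c(10, 10)), "multiply")
  expect_error(deep2d_spec(branch_kernels = c(1, 3)), "three")
  expect_error(deep2d_spec(branch_kernels = c(2, 3, 5)), "odd")
  expect_error(deepfc_spec(widths = c(128, 64, 1)), "exceed")
  expect_error(deepfc_spec(widths = c(512, 64, 64, 1)), "decreasing")
  expect_error(deepfc_spec(widths = c(512, 64, 2)), "final width")
  expect_error(deepfc_spec(dropout_rate = 1), "dropout_rate")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("Deep2D honours its shape and channel-arithmetic contracts", {
  spec <- deep2d_spec(branch_filters = c(4, 8, 16), fc_widths = c(8),
                      seed = 5)
  m <- build_deep2d(spec)
  X <- matrix(runif(4 * 256), 4, 256)
  out <- predict_deep(m, X)
  expect_length(out, 4L)
  # concatenated channel count = sum of branch filters
  inc <- m$layers[[1]]
  fw <- canopyspec:::.forward_deep(m, X)
  concat_width <- ncol(fw$cache[[2]]$A_in)
  expect_equal(concat_width, 256 * sum(spec$branch_filters))
  # two builds with the same seed give identical initial predictions
  expect_identical(out, predict_deep(build_deep2d(spec), X))
  expect_error(predict_deep(m, matrix(1, 2, 100)), "band count")
})

test_that("DeepFC evaluation is deterministic and all-linear stacks are affine", {
  spec <- deepfc_spec(seed = 8)
  m <- build_deepfc(spec)
  X <- matrix(runif(6 * 256), 6, 256)
  expect_identical(predict_deep(m, X), predict_deep(m, X))
  # compose the explicit affine map layer by layer
  W <- diag(256); b <- rep(0, 256)
  for (l in m$layers) {
    b <- as.vector(matrix(b, 1) %*% l$W) + l$b
    W <- W %*% l$W
  }
  expect_equal(predict_deep(m, X), as.vector(X %*% W) + b,
               tolerance = 1e-10)
})

test_that("dropout only acts in training mode and rate 0 is a no-op", {
  X <- matrix(runif(5 * 64), 5, 64)
  m0 <- build_deepfc(deepfc_spec(input_bands = 64,
                                 widths = c(128, 32, 1),
                                 dropout_rate = 0, seed = 2))
  set.seed(1)
  train_out <- canopyspec:::.forward_deep(m0, X, train = TRUE)$out
  eval_out <- canopyspec:::.forward_deep(m0, X, train = FALSE)$out
  expect_identical(train_out, eval_out)
  m5 <- build_deepfc(deepfc_spec(input_bands = 64,
                                 widths = c(128, 32, 1),
                                 dropout_rate = 0.5, seed = 2))
  set.seed(1)
  tr1 <- canopyspec:::.forward_deep(m5, X, train = TRUE)$out
  ev <- canopyspec:::.forward_deep(m5, X, train = FALSE)$out
  expect_false(identical(tr1, ev))
})

test_that("zero training epochs returns the initialization untouched", {
  g <- generate_spectra(generator_config(n_samples = 30, n_bands = 64,
                                         seed = 3))
  m <- build_deepfc(deepfc_spec(input_bands = 64, widths = c(128, 16, 1),
                                seed = 4))
  tr <- train_deep(m, g$spectra[1:20, ], g$traits$ssc[1:20],
                   g$spectra[21:30, ], g$traits$ssc[21:30],
                   train_config(max_epochs = 0, seed = 1))
  expect_identical(tr$layers, m$layers)
  expect_identical(tr$offset, 0)
  expect_equal(nrow(tr$history), 0L)
})

test_that("a zero-weight model predicts its output bias", {
  m <- build_deepfc(deepfc_spec(input_bands = 16, widths = c(32, 8, 1),
                                dropout_rate = 0, seed = 1))
  m$layers <- lapply(m$layers, function(l) { l$W[] <- 0; l })
  m$layers[[3]]$b <- 4.25
  X <- matrix(runif(3 * 16), 3, 16)
  expect_equal(predict_deep(m, X), rep(4.25, 3))
})

test_that("training is seed-reproducible and early stopping keeps the best epoch", {
  g <- generate_spectra(generator_config(n_samples = 60, n_bands = 64,
                                         seed = 12))
  y <- g$traits$ssc
  spec <- deepfc_spec(input_bands = 64, widths = c(96, 16, 1), seed = 3)
  cfg <- train_config(max_epochs = 20, patience = 20, seed = 9)
  t1 <- train_deep(build_deepfc(spec), g$spectra[1:40, ], y[1:40],
                   g$spectra[41:60, ], y[41:60], cfg)
  t2 <- train_deep(build_deepfc(spec), g$spectra[1:40, ], y[1:40],
                   g$spectra[41:60, ], y[41:60], cfg)
  expect_identical(t1$layers, t2$layers)
  expect_identical(t1$history, t2$history)
  # returned weights reproduce the recorded best validation RMSE exactly
  pv <- predict_deep(t1, g$spectra[41:60, ])
  expect_equal(sqrt(mean((pv - y[41:60])^2)),
               min(t1$history$val_rmse), tolerance = 1e-12)
  expect_equal(t1$best_epoch, which.min(t1$history$val_rmse))
  # batch-of-one prediction equals batched prediction
  single <- vapply(41:44, function(i)
    predict_deep(t1, g$spectra[i, ]), numeric(1))
  expect_equal(single, predict_deep(t1, g$spectra[41:44, ]),
               tolerance = 1e-12)
})

test_that("training refuses overlapping calibration/validation ids", {
  g <- generate_spectra(generator_config(n_samples = 20, n_bands = 64,
                                         seed = 2))
  m <- build_deepfc(deepfc_spec(input_bands = 64, widths = c(96, 8, 1)))
  expect_error(
    train_deep(m, g$spectra[1:12, ], g$traits$ssc[1:12],
               g$spectra[10:20, ], g$traits$ssc[10:20],
               train_config(max_epochs = 1)),
    "disjoint")
})

test_that("training history is written as CSV", {
  g <- generate_spectra(generator_config(n_samples = 30, n_bands = 64,
                                         seed = 5))
  m <- train_deep(build_deepfc(deepfc_spec(input_bands = 64,
                                           widths = c(96, 8, 1), seed = 1)),
                  g$spectra[1:20, ], g$traits$ssc[1:20],
                  g$spectra[21:30, ], g$traits$ssc[21:30],
                  train_config(max_epochs = 3, seed = 2))
  p <- tempfile(fileext = ".csv")
  write_history(m, p)
  h <- read.csv(p)
  expect_equal(nrow(h), 3L)
  expect_named(h, c("epoch", "train_rmse", "val_rmse", "train_mae",
                    "val_mae"))
})
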