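test_that("PLSR hits the exact-fit limit and matches a hand NIPALS iteration", {
  set.seed(1)
  X <- matrix(rnorm(30 * 4), 30, 4)
  beta <- c(1, -2, 0.5, 3)
  y <- as.vector(X %*% beta) + 1
  fit <- fit_plsr(X, y, 4)
  expect_equal(unname(predict(fit, X)), y, tolerance = 1e-8)
  # independent single-component PLS1 arithmetic on a 4 x 3 hand dataset
  Xh <- matrix(c(1, 2, 3, 4,
                 0, 1, 0, 1,
                 2, 0, 1, 1), 4, 3)
  yh <- c(0.5, 1.5, 2, 3.5)
  Xc <- scale(Xh, scale = FALSE); yc <- yh - mean(yh)
  w <- crossprod(Xc, yc); w <- w / sqrt(sum(w^2))
  tt <- Xc %*% w
  q <- sum(yc * tt) / sum(tt^2)
  b_hand <- as.vector(w * q)
  fit1 <- fit_plsr(Xh, yh, 1)
  expect_equal(fit1$coef, b_hand, tolerance = 1e-12)
  expect_equal(fit1$intercept, mean(yh) - sum(colMeans(Xh) * b_hand),
               tolerance = 1e-12)
  expect_error(fit_plsr(matrix(1, 10, 3), rnorm(10), 2), "degenerate")
  expect_error(fit_plsr(X, y, 0), "n_components")
})

test_that("full-component PLSR coincides with MLR normal equations", {
  set.seed(2)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- as.vector(X %*% rnorm(6)) + 2 + rnorm(50, 0, 0.2)
  pm <- fit_plsr(X, y, 6)
  mm <- fit_mlr(X, y)
  expect_equal(pm$coef, mm$coef, tolerance = 1e-8)
  expect_equal(pm$intercept, mm$intercept, tolerance = 1e-8)
})

test_that("PLSR agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(9)
  X <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(NULL, paste0("b", 1:10)))
  y <- as.vector(X %*% rnorm(10)) + rnorm(40, 0, 0.3)
  mine <- fit_plsr(X, y, 3)
  ext <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  pred_ext <- predict(ext, X)$predict[, 1, 3]
  expect_equal(unname(predict(mine, X)), unname(pred_ext), tolerance = 1e-6)
})

test_that("MLR solves the hand cases and flags degeneracy", {
  x <- matrix(1:10)
  m <- fit_mlr(x, 2 * (1:10) + 3)
  expect_equal(m$coef, 2)
  expect_equal(m$intercept, 3)
  expect_equal(unname(predict(m, matrix(5))), 13)
  # constant response: zero slopes, intercept = mean
  m0 <- fit_mlr(matrix(rnorm(20), 10, 2), rep(4, 10))
  expect_equal(m0$coef, c(0, 0), tolerance = 1e-12)
  expect_equal(m0$intercept, 4)
  # duplicated column -> minimum-norm solution, flagged
  set.seed(3)
  z <- rnorm(12)
  Xd <- cbind(z, z)
  expect_warning(md <- fit_mlr(Xd, 3 * z + 1), "rank-deficient")
  expect_true(md$pseudo_inverse)
  expect_equal(md$coef, c(1.5, 1.5), tolerance = 1e-8)
})

test_that("LWR interpolates, recovers the global limit, and beats MLR on curves", {
  set.seed(4)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- as.vector(X %*% rnorm(5)) + rnorm(40, 0, 0.1)
  glob <- fit_lwr(X, y, neighborhood = 40, n_components = 3,
                  weights = "uniform")
  pls3 <- fit_plsr(X, y, 3)
  expect_equal(unname(predict(glob, X)), unname(predict(pls3, X)),
               tolerance = 1e-8)
  # nearest-neighbour interpolation limit
  near <- fit_lwr(X, y, neighborhood = 1, n_components = 1)
  expect_equal(unname(predict(near, X[7, , drop = FALSE])), y[7])
  # curved 1-D response: local model beats the global line
  xs <- matrix(seq(0, 2 * pi, length.out = 50))
  ys <- sin(xs[, 1])
  lw <- fit_lwr(xs, ys, neighborhood = 10, n_components = 1)
  ml <- fit_mlr(xs, ys)
  expect_lt(rmse(predict(lw, xs), ys), rmse(predict(ml, xs), ys))
  expect_warning(fit_lwr(X, y, neighborhood = 99, n_components = 2),
                 "clipped")
})

test_that("ANN fits linear responses, is seeded, and honours zero epochs", {
  set.seed(5)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- as.vector(X %*% c(1, 2, -1, 0.5)) + 3
  fit <- fit_ann(X, y, hidden = 8, epochs = 500, seed = 11)
  expect_gte(r_squared(predict(fit, X), y), 0.99)
  # determinism
  f2 <- fit_ann(X, y, hidden = 8, epochs = 500, seed = 11)
  expect_identical(predict(fit, X), predict(f2, X))
  # zero epochs: predictions come from the seeded initialization
  u0 <- fit_ann(X, y, hidden = 8, epochs = 0, seed = 11)
  u0b <- fit_ann(X, y, hidden = 8, epochs = 0, seed = 11)
  expect_identical(u0$net$wts, u0b$net$wts)
  expect_lt(r_squared(predict(u0, X), y), 0.5)  # untrained
})

test_that("SVR honours the insensitive-tube contracts", {
  set.seed(6)
  X <- matrix(rnorm(30 * 3), 30, 3)
  y <- as.vector(X %*% c(2, -1, 0.5)) + 1
  # epsilon beyond the response range: flat predictor, zero slack
  eps <- diff(range(y)) + 1
  flat <- fit_svr(X, y, epsilon = eps)
  pr <- predict(flat, X)
  expect_equal(sd(pr), 0)
  expect_true(all(abs(pr - y) <= eps + 1e-8))
  expect_equal(flat$n_support, 0L)
  # linear-kernel, large cost: residuals within the tube (KKT)
  hard <- fit_svr(X, y, kernel = "linear", cost = 1000, epsilon = 0.25)
  expect_true(all(abs(predict(hard, X) - y) <= 0.25 + 1e-3))
  # duplicated rows predict identically
  Xd <- rbind(X, X[1, ])
  yd <- c(y, y[1])
  dup <- fit_svr(Xd, yd)
  expect_equal(predict(dup, Xd)[1], predict(dup, Xd)[31])
  expect_error(fit_svr(X, y, cost = -1), "cost")
  expect_error(fit_svr(X, y, epsilon = -1), "epsilon")
})

test_that("predict enforces the band contract across families", {
  sm <- tiny_spectra(20, 12)
  y <- rowMeans(sm$values)
  fits <- list(fit_plsr(sm, y, 3), fit_mlr(sm, y),
               fit_lwr(sm, y, 8, 2), fit_svr(sm, y))
  wrong <- tiny_spectra(2, 10)
  for (f in fits) {
    expect_error(predict(f, wrong), "mismatch")
    expect_length(predict(f, matrix(numeric(0), 0, 12)), 0L)
  }
  shifted <- sm
  shifted$wavelengths <- sm$wavelengths + 5
  expect_error(predict(fits[[1]], shifted), "wavelengths")
})

test_that("band permutation applied consistently leaves predictions unchanged", {
  set.seed(7)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- as.vector(X %*% rnorm(8)) + rnorm(30, 0, 0.1)
  Xq <- matrix(rnorm(5 * 8), 5, 8)
  perm <- sample(8)
  for (fitter in list(function(A, b) fit_plsr(A, b, 4),
                      fit_mlr,
                      function(A, b) fit_lwr(A, b, 12, 3))) {
    base <- predict(fitter(X, y), Xq)
    permuted <- predict(fitter(X[, perm], y), Xq[, perm])
    expect_equal(base, permuted, tolerance = 1e-8)
  }
})

test_that("linear models serialize their coefficients", {
  sm <- tiny_spectra(10, 6)
  y <- rnorm(10)
  p <- tempfile(fileext = ".json")
  write_model(fit_plsr(sm, y, 2), p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$family, "PLSR")
  expect_length(back$coef, 6L)
})
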