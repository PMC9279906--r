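test_that("moving window smoothing matches hand averages and edge shrinkage", {
  v <- spectra_matrix(matrix(c(1, 2, 3, 4, 5), 1))
  out <- mws(v, 3)
  expect_equal(out$values[1, 2:4], c(2, 3, 4))   # interior hand averages
  expect_equal(out$values[1, c(1, 5)], c(1, 5))  # shrunken edge windows
  expect_equal(out$treatment, "MWS")
  expect_equal(mws(v, 1)$values, v$values)       # window 1 = identity
  const <- spectra_matrix(matrix(2, 3, 9))
  expect_equal(mws(const, 5)$values, const$values)
  expect_error(mws(v, 4), "odd")
  expect_error(mws(v, -3), "odd")
  expect_error(mws(v, 7), "exceeds")
})

test_that("Savitzky-Golay reproduces the closed-form impulse weights", {
  imp <- spectra_matrix(matrix(c(0, 0, 1, 0, 0), 1))
  out <- savgol(imp, window = 5, order = 2, deriv = 0)
  expect_equal(out$values[1, ], c(-3, 12, 17, 12, -3) / 35)
  expect_equal(out$values[1, 3], 17 / 35)
})

test_that("Savitzky-Golay reproduces polynomials and differentiates ramps", {
  x <- seq_len(21)
  quad <- spectra_matrix(matrix(0.5 * x^2 - 3 * x + 1, 1))
  sm <- savgol(quad, 7, 2, 0)
  expect_equal(sm$values, quad$values, tolerance = 1e-10)  # degree <= order
  ramp <- spectra_matrix(matrix(2 * x + 5, 1))
  expect_equal(savgol(ramp, 5, 2, 0)$values, ramp$values, tolerance = 1e-10)
  expect_equal(savgol(ramp, 5, 2, 1)$values[1, ], rep(2, 21),
               tolerance = 1e-10)
  expect_error(savgol(ramp, 5, 5, 0), "smaller")
  expect_error(savgol(ramp, 5, 2, 3), "deriv")
})

test_that("smoothers are linear operators and commute with row permutation", {
  set.seed(8)
  x <- matrix(runif(4 * 32), 4, 32)
  y <- matrix(runif(4 * 32), 4, 32)
  a <- 1.7; b <- -0.4
  for (f in list(function(m) mws(spectra_matrix(m), 5)$values,
                 function(m) savgol(spectra_matrix(m), 7, 2, 0)$values)) {
    expect_equal(f(a * x + b * y), a * f(x) + b * f(y), tolerance = 1e-10)
  }
  perm <- c(3, 1, 4, 2)
  for (f in list(function(m) mws(spectra_matrix(m), 5)$values,
                 function(m) savgol(spectra_matrix(m), 7, 2, 1)$values,
                 function(m) derivative(spectra_matrix(m), 2)$values,
                 function(m) wavelet_denoise(spectra_matrix(m))$values)) {
    expect_equal(f(x)[perm, ], f(x[perm, ]), tolerance = 1e-12)
  }
})

test_that("Savitzky-Golay noise variance shrinks by the sum of squared weights", {
  w <- c(-3, 12, 17, 12, -3) / 35
  set.seed(21)
  noise <- matrix(rnorm(8 * 4000), 8, 4000)
  sm <- savgol(spectra_matrix(noise, seq_len(4000) * 1.0), 5, 2, 0)$values
  ratio <- var(as.vector(sm[, 3:3998])) / var(as.vector(noise))
  expect_equal(ratio, sum(w^2), tolerance = 0.02)
})

test_that("finite-difference derivatives behave on constants and ramps", {
  B <- 12
  const <- spectra_matrix(matrix(4, 1, B))
  expect_equal(derivative(const, 1)$values, matrix(0, 1, B))
  expect_equal(derivative(const, 1)$treatment, "FDR")
  s <- 0.25
  ramp <- spectra_matrix(matrix(s * seq_len(B), 1))
  d1 <- derivative(ramp, 1)
  expect_equal(d1$values, matrix(s, 1, B))     # incl. repeated-tail padding
  d2 <- derivative(ramp, 2)
  expect_equal(d2$values, matrix(0, 1, B))
  expect_equal(d2$treatment, "SDR")
  expect_error(derivative(ramp, 3), "1 or 2")
  expect_error(derivative(spectra_matrix(matrix(1, 1, 2)), 2), "too few")
})

test_that("wavelet transform reconstructs perfectly and denoises", {
  B <- 256
  z <- spectra_matrix(matrix(0, 1, B))
  expect_equal(wavelet_denoise(z)$values, z$values)
  smooth <- sin(seq(0, 4 * pi, length.out = B)) + 0.5
  # rule "none" is pure analysis/synthesis
  for (fam in c("haar", "db2", "db4")) {
    pr <- wavelet_denoise(spectra_matrix(matrix(smooth, 1)), family = fam,
                          rule = "none")
    expect_equal(pr$values[1, ], smooth, tolerance = 1e-10)
  }
  # non-dyadic length via reflection padding
  odd <- smooth[1:100]
  pr2 <- wavelet_denoise(spectra_matrix(matrix(odd, 1)), rule = "none")
  expect_equal(pr2$values[1, ], odd, tolerance = 1e-10)
  # seeded denoising oracle: output closer to clean than input
  set.seed(33)
  noisy <- smooth + rnorm(B, 0, 0.05)
  den <- wavelet_denoise(spectra_matrix(matrix(noisy, 1)))
  expect_lt(sqrt(mean((den$values[1, ] - smooth)^2)),
            sqrt(mean((noisy - smooth)^2)))
  expect_equal(den$treatment, "WT")
  expect_error(wavelet_denoise(spectra_matrix(matrix(1, 1, 4)), level = 5),
               "infeasible")
})

test_that("pretreat dispatches by tag", {
  sm <- tiny_spectra(3, 32)
  expect_identical(pretreat(sm, "raw"), sm)
  expect_equal(pretreat(sm, "SDR")$treatment, "SDR")
  expect_equal(pretreat(sm, "WT")$treatment, "WT")
  expect_error(pretreat(sm, "SNV"), "unknown pretreatment")
})
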