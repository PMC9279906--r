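test_that("the canopy template shows the expected vegetation features", {
  wl <- seq(400, 1000, length.out = 256)
  r <- base_canopy_curve(wl)
  expect_true(all(r > 0 & r < 1))
  # red-edge ordering
  expect_gt(r[which.min(abs(wl - 760))], r[which.min(abs(wl - 680))])
  # deterministic
  expect_identical(r, base_canopy_curve(wl))
  # local maximum (green peak) inside 515-650 nm
  win <- wl > 515 & wl < 650
  peak <- which(win)[which.max(r[win])]
  expect_gt(r[peak], r[peak - 1]); expect_gt(r[peak], r[peak + 1])
  # local minimum (water dip) inside 960-1000 nm
  win2 <- wl > 960 & wl <= 1000
  dip <- which(win2)[which.min(r[win2])]
  expect_lt(r[dip], r[dip - 1]); expect_lt(r[dip], r[dip + 1])
  expect_error(base_canopy_curve(c(350, 500)), "400-1000")
})

test_that("generator honours its determinism and noise contracts", {
  cfg <- generator_config(n_samples = 40, seed = 5)
  a <- generate_spectra(cfg); b <- generate_spectra(cfg)
  expect_identical(a$spectra$values, b$spectra$values)
  expect_identical(a$traits, b$traits)
  # zero randomness in the spectral model: equal traits give equal spectra
  cfg0 <- generator_config(n_samples = 10, noise_sd = 0, scatter_sd = 0,
                           baseline_slope_sd = 0, seed = 6)
  g0 <- generate_spectra(cfg0)
  ord <- order(g0$traits$ssc)
  i <- ord[1]
  # rebuild a sample's spectrum from the recorded truth: same trait -> same row
  same <- which(abs(g0$traits$ssc - g0$traits$ssc[i]) < 1e-12 &
                  abs(g0$traits$ph - g0$traits$ph[i]) < 1e-12)
  for (j in same)
    expect_equal(g0$spectra$values[j, ], g0$spectra$values[i, ])
})

test_that("trait sampling matches the configured distribution", {
  g <- generate_spectra(generator_config(seed = 31))
  ssc <- g$traits$ssc
  expect_length(ssc, 387L)
  cfg <- generator_config()
  rng <- cfg$trait_distributions$ssc$range
  expect_true(all(ssc >= rng[1] & ssc <= rng[2]))
  se <- sqrt(cfg$trait_distributions$ssc$variance / 387)
  expect_lt(abs(mean(ssc) - cfg$trait_distributions$ssc$mean), 3 * se)
  expect_error(
    generator_config(trait_distributions = list(
      t1 = list(mean = 0, variance = 1e-6, range = c(-5, 5))),
      absorption_features = list(absorption_feature(700, 20, "t1"))),
    NA)
  expect_error(
    generator_config(trait_distributions = list(
      t1 = list(mean = 10, variance = 1, range = c(0, 5))),
      absorption_features = list()),
    "contain the trait mean")
  expect_error(
    generator_config(absorption_features = list(
      absorption_feature(1200, 20, "ssc"))),
    "outside the wavelength range")
})

test_that("generated spectra are learnable by PLSR over a KS split", {
  g <- generate_spectra(generator_config(seed = 77))
  y <- g$traits$ssc
  split <- split_samples(g$spectra, seed = 77)
  fit <- fit_plsr(g$spectra[split$calibration, ], y[split$calibration], 10)
  expect_gte(r_squared(predict(fit, g$spectra[split$prediction, ]),
                       y[split$prediction]), 0.8)
})

test_that("more noise never helps a fixed model", {
  r2_at <- function(noise) {
    cfg <- generator_config(n_samples = 120, noise_sd = noise, seed = 50)
    g <- generate_spectra(cfg)
    y <- g$traits$ssc
    split <- split_samples(g$spectra, seed = 50)
    fit <- fit_plsr(g$spectra[split$calibration, ], y[split$calibration], 8)
    rmse(predict(fit, g$spectra[split$prediction, ]), y[split$prediction])
  }
  expect_lt(r2_at(0.001), r2_at(0.03))
})

test_that("synthetic cubes honour fraction, determinism and noiseless recovery", {
  plant <- base_canopy_curve(seq(400, 1000, length.out = 16))
  bg <- rep(0.15, 16)
  gen <- generate_cube(plant, bg, shape = c(100, 100), canopy_fraction = 0.5,
                       noise_sd = 0.005, seed = 8)
  expect_equal(sum(gen$mask), 5000L)
  gen2 <- generate_cube(plant, bg, shape = c(100, 100), canopy_fraction = 0.5,
                        noise_sd = 0.005, seed = 8)
  expect_identical(gen$cube$data, gen2$cube$data)
  # noiseless cube: SAM with a small threshold recovers the exact mask
  clean <- generate_cube(plant, bg, shape = c(24, 24), canopy_fraction = 0.3,
                         noise_sd = 0, seed = 9)
  got <- classify_sam(clean$cube,
                      endmember_set(rbind(plant, bg),
                                    c("plant", "background")),
                      threshold = 0.05)
  expect_identical(got$mask, clean$mask)
  expect_error(generate_cube(plant, bg[1:4], c(10, 10), 0.5, 0, 1),
               "equal length")
  expect_error(generate_cube(plant, bg, c(10, 10), 1.2, 0, 1),
               "canopy_fraction")
  expect_error(generate_cube(plant, bg, c(1, 10), 0.5, 0, 1), "degenerate")
})

test_that("sparse-band benchmark records exact ground truth", {
  sb <- generate_sparse_bands(100, 50, 8, snr = 25, seed = 13)
  expect_length(sb$informative, 8L)
  expect_length(sb$coef, 8L)
  sb2 <- generate_sparse_bands(100, 50, 8, snr = 25, seed = 13)
  expect_identical(sb$y, sb2$y)
  # stated signal-to-noise is honoured approximately
  signal <- as.vector(sb$spectra$values[, sb$informative] %*% sb$coef)
  expect_equal(var(signal) / var(sb$y - signal), 25, tolerance = 0.5)
})
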