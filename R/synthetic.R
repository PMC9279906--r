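#' @name synthetic_data
#' @title Synthetic canopy spectra with known trait structure
#'
#' @description A seeded generator of canopy-like mean-reflectance spectra
#' and paired biochemical traits, built so every pipeline stage (from
#' segmentation on synthetic cubes through deep-model training) is testable
#' without field data. Traits follow truncated normal distributions
#' matching the reference statistics of the emulated crop; spectra are a
#' deterministic canopy template modulated by trait-linked Gaussian
#' absorption features plus multiplicative scatter, baseline tilt and white
#' noise. The trait-to-feature links are recorded as ground truth so
#' wavelength-selection recovery can be scored exactly.
NULL

#' Deterministic canopy reflectance template
#'
#' A smooth vegetation-like Vis-NIR reflectance curve: low blue, a green
#' peak near 550 nm, a chlorophyll trough near 680 nm, a steep red edge
#' through 710-760 nm, an NIR plateau and a water-related dip near 980 nm.
#' Values lie in (0, 1) and the curve carries no randomness.
#'
#' @param wavelengths nm vector within 400-1000.
#' @return Reflectance vector of the same length.
#' @export
base_canopy_curve <- function(wavelengths) {
  if (any(wavelengths < 400 | wavelengths > 1000))
    stop("wavelengths must lie within 400-1000 nm")
  0.04 +
    0.055 * exp(-((wavelengths - 550)^2) / (2 * 35^2)) +
    0.42 * stats::plogis((wavelengths - 730) / 12) -
    0.05 * exp(-((wavelengths - 980)^2) / (2 * 22^2))
}

#' Trait-linked absorption feature
#'
#' @param center feature centre in nm.
#' @param width Gaussian width (sd) in nm.
#' @param trait name of the linked trait.
#' @param link \code{"linear"} (depth proportional to the standardized
#'   trait) or \code{"quadratic"} (depth proportional to the squared
#'   range-normalized trait: monotone but curved, so linear models
#'   underfit it).
#' @param strength depth scale in reflectance units.
#' @return A list describing the feature.
#' @export
absorption_feature <- function(center, width, trait, link = "linear",
                               strength = 0.03) {
  link <- match.arg(link, c("linear", "quadratic"))
  list(center = center, width = width, trait = trait, link = link,
       strength = strength)
}

#' Synthetic generator configuration
#'
#' Defaults emulate a field trait-calibration campaign on lettuce-like
#' canopies: 387 samples, 256 bands over 400-1000 nm, an SSC-like trait
#' (mean 3.1040, variance 0.5667, range 0.8750-5.8250) driving
#' near-infrared water-feature depths, and a weaker pH-like trait (mean
#' 6.5945, variance 0.0074, range 6.3125-6.8175) with a fainter visible
#' link. Noise defaults reflect canopy mean spectra, which average
#' thousands of pixels and are therefore smooth: additive white noise sd
#' 0.002 reflectance, 2% multiplicative scatter, mild baseline tilt.
#'
#' @param n_samples number of samples (default 387).
#' @param n_bands number of bands (default 256).
#' @param wavelength_range nm range (default 400-1000).
#' @param trait_distributions named list of per-trait
#'   \code{list(mean, variance, range)}.
#' @param absorption_features list of [absorption_feature]s; centres must
#'   lie inside \code{wavelength_range}.
#' @param noise_sd additive white noise sd (reflectance units).
#' @param scatter_sd sd of the multiplicative scatter factor around 1.
#' @param baseline_slope_sd sd of the additive linear baseline slope
#'   (reflectance units across the full range).
#' @param seed integer seed.
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(
    n_samples = 387L, n_bands = 256L, wavelength_range = c(400, 1000),
    trait_distributions = list(
      ssc = list(mean = 3.1040, variance = 0.5667, range = c(0.8750, 5.8250)),
      ph = list(mean = 6.5945, variance = 0.0074, range = c(6.3125, 6.8175))),
    absorption_features = list(
      absorption_feature(980, 25, "ssc", "linear", 0.035),
      absorption_feature(880, 40, "ssc", "linear", 0.015),
      absorption_feature(580, 30, "ph", "linear", 0.008)),
    noise_sd = 0.002, scatter_sd = 0.02, baseline_slope_sd = 0.005,
    seed = 1L) {
  for (tr in trait_distributions) {
    if (tr$range[1] > tr$mean || tr$range[2] < tr$mean)
      stop("trait range must contain the trait mean")
    sdv <- sqrt(tr$variance)
    if (tr$range[2] < tr$mean - 6 * sdv || tr$range[1] > tr$mean + 6 * sdv)
      stop("infeasible truncation: range excludes mean +/- 6 sd")
  }
  for (f in absorption_features) {
    if (f$center < wavelength_range[1] || f$center > wavelength_range[2])
      stop("feature centre outside the wavelength range")
    if (!f$trait %in% names(trait_distributions))
      stop("feature linked to unknown trait: ", f$trait)
  }
  if (noise_sd < 0 || scatter_sd < 0 || baseline_slope_sd < 0)
    stop("noise/scatter/baseline sds must be nonnegative")
  structure(list(n_samples = as.integer(n_samples),
                 n_bands = as.integer(n_bands),
                 wavelength_range = wavelength_range,
                 trait_distributions = trait_distributions,
                 absorption_features = absorption_features,
                 noise_sd = noise_sd, scatter_sd = scatter_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# truncated normal by reject-and-resample
.rtruncnorm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  out[seq_len(n)]
}

.feature_depth <- function(feature, trait_values, dist) {
  if (feature$link == "linear") {
    z <- (trait_values - dist$mean) / sqrt(dist$variance)
    feature$strength * z
  } else {
    q <- (trait_values - dist$range[1]) / diff(dist$range)
    feature$strength * q^2
  }
}

#' Generate synthetic canopy spectra and traits
#'
#' Each spectrum is
#' \code{scatter * (base - sum(depth_f(trait) * Gaussian(center, width)))
#' + baseline + noise}, with traits drawn from truncated normals. The
#' returned ground truth records every trait-feature link (including the
#' per-feature informative band set) for recovery tests.
#'
#' @param config a [generator_config].
#' @return A list: \code{$spectra} ([spectra_matrix]), \code{$traits}
#'   (data.frame with \code{id} plus one column per trait), \code{$truth}
#'   (feature links, informative band indices, seed).
#' @export
generate_spectra <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    n <- config$n_samples
    wl <- seq(config$wavelength_range[1], config$wavelength_range[2],
              length.out = config$n_bands)
    base <- base_canopy_curve(wl)
    traits <- lapply(config$trait_distributions, function(tr)
      .rtruncnorm(n, tr$mean, sqrt(tr$variance), tr$range))
    V <- matrix(rep(base, each = n), n, config$n_bands)
    informative <- list()
    for (f in config$absorption_features) {
      g <- exp(-((wl - f$center)^2) / (2 * f$width^2))
      depth <- .feature_depth(f, traits[[f$trait]],
                              config$trait_distributions[[f$trait]])
      V <- V - outer(depth, g)
      informative[[length(informative) + 1L]] <-
        list(trait = f$trait, link = f$link,
             bands = which(g > 0.1))
    }
    scatter <- 1 + stats::rnorm(n, 0, config$scatter_sd)
    slope <- stats::rnorm(n, 0, config$baseline_slope_sd)
    tilt <- (wl - mean(wl)) / diff(range(wl))
    V <- V * scatter + outer(slope, tilt) +
      matrix(stats::rnorm(n * config$n_bands, 0, config$noise_sd),
             n, config$n_bands)
    ids <- sprintf("SYN%04d", seq_len(n))
    list(spectra = spectra_matrix(V, wl, ids),
         traits = data.frame(id = ids, as.data.frame(traits),
                             stringsAsFactors = FALSE),
         truth = list(features = config$absorption_features,
                      informative = informative, seed = config$seed))
  })
}

#' Generate a sparse-band regression benchmark
#'
#' Spectra-like predictors where the response depends on exactly `k`
#' informative bands, at a stated signal-to-noise ratio. This is the exact
#' ground truth used to score wavelength-selection support recovery.
#'
#' @param n samples, \code{p} bands, \code{k} informative bands.
#' @param p number of bands.
#' @param k number of informative bands.
#' @param snr signal-to-noise ratio (variance ratio) of the response.
#' @param seed integer seed.
#' @return List: \code{$spectra} ([spectra_matrix]), \code{$y},
#'   \code{$informative} (band indices), \code{$coef}.
#' @export
generate_sparse_bands <- function(n = 200L, p = 200L, k = 10L, snr = 20,
                                  seed = 1L) {
  .with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    # mild neighbour correlation, as adjacent bands have
    X <- X + 0.5 * cbind(X[, -1], X[, p]) + 0.5 * cbind(X[, 1], X[, -p])
    informative <- sort(sample.int(p, k))
    beta <- stats::runif(k, 0.5, 1.5) * sample(c(-1, 1), k, replace = TRUE)
    signal <- as.vector(X[, informative, drop = FALSE] %*% beta)
    noise_sd <- sqrt(stats::var(signal) / snr)
    y <- signal + stats::rnorm(n, 0, noise_sd)
    list(spectra = spectra_matrix(X, seq_len(p) * 1.0), y = y,
         informative = informative, coef = beta)
  })
}

#' Generate a synthetic segmentation cube
#'
#' Builds a calibrated cube whose pixels carry either the plant or the
#' background spectrum plus noise, with the plant region grown as a single
#' seeded blob of exactly \code{round(canopy_fraction * lines * samples)}
#' pixels. The true mask is returned for segmentation scoring.
#'
#' @param plant_spectrum,background_spectrum reflectance vectors of equal
#'   length.
#' @param shape \code{c(lines, samples)}.
#' @param canopy_fraction plant pixel fraction in (0, 1).
#' @param noise_sd additive white noise sd.
#' @param seed integer seed.
#' @return List: \code{$cube} (calibrated [hypercube]), \code{$mask}
#'   (logical ground-truth matrix).
#' @export
generate_cube <- function(plant_spectrum, background_spectrum,
                          shape = c(64L, 64L), canopy_fraction = 0.3,
                          noise_sd = 0.005, seed = 1L) {
  if (length(plant_spectrum) != length(background_spectrum))
    stop("plant and background spectra must have equal length")
  if (canopy_fraction <= 0 || canopy_fraction >= 1)
    stop("`canopy_fraction` must be in (0, 1)")
  if (any(shape < 2L)) stop("degenerate cube shape")
  nl <- shape[1]; ns <- shape[2]; nb <- length(plant_spectrum)
  target <- round(canopy_fraction * nl * ns)
  if (target < 1L) stop("`canopy_fraction` yields no plant pixels")
  .with_seed(seed, {
    mask <- matrix(FALSE, nl, ns)
    start <- c(ceiling(nl / 2), ceiling(ns / 2))
    mask[start[1], start[2]] <- TRUE
    frontier <- matrix(start, ncol = 2)
    nbrs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    count <- 1L
    while (count < target) {
      # candidate neighbours of the current blob
      cand <- do.call(rbind, lapply(seq_len(4), function(d)
        sweep(frontier, 2L, nbrs[d, ], `+`)))
      ok <- cand[, 1] >= 1 & cand[, 1] <= nl & cand[, 2] >= 1 & cand[, 2] <= ns
      cand <- cand[ok, , drop = FALSE]
      cand <- cand[!mask[cand], , drop = FALSE]
      if (!nrow(cand)) break
      cand <- unique(cand)
      take <- cand[sample.int(nrow(cand),
                              min(nrow(cand), target - count)), , drop = FALSE]
      mask[take] <- TRUE
      count <- count + nrow(take)
      frontier <- take
      if (count < target && !nrow(frontier)) break
    }
    # frontier growth can stall on a full wavefront; top up from any border
    while (count < target) {
      all_idx <- which(!mask)
      mask[all_idx[sample.int(length(all_idx), 1L)]] <- TRUE
      count <- count + 1L
    }
    arr <- array(0, c(nl, ns, nb))
    flat <- matrix(rep(background_spectrum, each = nl * ns), nl * ns, nb)
    flat[as.vector(mask), ] <- matrix(rep(plant_spectrum, each = sum(mask)),
                                      sum(mask), nb)
    flat <- flat + matrix(stats::rnorm(length(flat), 0, noise_sd),
                          nrow(flat), nb)
    arr <- array(flat, c(nl, ns, nb))
    list(cube = hypercube(arr, calibrated = TRUE,
                          meta = list(synthetic = TRUE)),
         mask = mask)
  })
}
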