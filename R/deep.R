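#' @name deep_models
#' @title Purpose-built neural spectral regressors
#'
#' @description Two end-to-end regressors that map a raw mean-reflectance
#' spectrum directly to a trait value, with no pretreatment or wavelength
#' selection:
#' \describe{
#'   \item{Deep2D}{the spectrum is reshaped row-major onto a small 2-D
#'     grid and passed through three parallel convolutional branches at
#'     different kernel scales (an Inception-style multi-scale block, ELU
#'     activations); the branch outputs are channel-concatenated, flattened
#'     and reduced to a scalar by linear fully connected layers.}
#'   \item{DeepFC}{a fully connected stack that first scales the feature
#'     dimension up beyond the band count and then contracts it to a
#'     scalar, with dropout on the first two hidden layers; hidden
#'     activations are linear by default (a nonlinear override is
#'     available).}
#' }
#' Both are trained with Adam on an RMSE objective (MAE tracked as the
#' secondary metric), with early stopping on validation RMSE.
NULL

# ---- specs ---------------------------------------------------------------

#' Deep2D architecture specification
#'
#' @param input_bands spectrum length B (default 256).
#' @param grid_shape 2-D reshape of the spectrum, \code{prod == B}
#'   (default 16 x 16, row-major).
#' @param branch_kernels three odd kernel sizes (default 1, 3, 5).
#' @param branch_filters filters per branch (default 16 each).
#' @param fc_widths hidden widths of the fully connected reduction; a
#'   final width-1 output layer is appended (default 32, 16).
#' @param seed integer seed for weight initialization.
#' @return An object of class \code{deep2d_spec}.
#' @export
deep2d_spec <- function(input_bands = 256L, grid_shape = c(16L, 16L),
                        branch_kernels = c(1L, 3L, 5L),
                        branch_filters = c(16L, 16L, 16L),
                        fc_widths = c(32L, 16L), seed = 1L) {
  if (length(branch_kernels) != 3L)
    stop("Deep2D uses exactly three convolutional branches")
  if (any(branch_kernels %% 2L == 0L))
    stop("`branch_kernels` must be odd (same-padding convolution)")
  if (length(branch_filters) == 1L) branch_filters <- rep(branch_filters, 3L)
  if (prod(grid_shape) != input_bands)
    stop("`grid_shape` must multiply to `input_bands`")
  structure(list(input_bands = as.integer(input_bands),
                 grid_shape = as.integer(grid_shape),
                 branch_kernels = as.integer(branch_kernels),
                 branch_filters = as.integer(branch_filters),
                 fc_widths = as.integer(fc_widths),
                 conv_activation = "elu", fc_activation = "linear",
                 seed = as.integer(seed)),
            class = "deep2d_spec")
}

#' DeepFC architecture specification
#'
#' @param input_bands spectrum length B (default 256).
#' @param widths hidden-layer widths ending in 1; the first must exceed
#'   \code{input_bands} (scale up) and the tail must be strictly
#'   decreasing (scale down). Default 512, 256, 64, 16, 1.
#' @param dropout_rate dropout applied to the first two hidden layers
#'   during training (default 0.1).
#' @param activation hidden activation, \code{"linear"} by default (the
#'   architecture's stated choice; the composed map is then affine) with
#'   \code{"elu"} available as an override.
#' @param seed integer seed for weight initialization.
#' @return An object of class \code{deepfc_spec}.
#' @export
deepfc_spec <- function(input_bands = 256L,
                        widths = c(512L, 256L, 64L, 16L, 1L),
                        dropout_rate = 0.1,
                        activation = c("linear", "elu"), seed = 1L) {
  activation <- match.arg(activation)
  widths <- as.integer(widths)
  if (widths[1] <= input_bands)
    stop("first hidden width must exceed `input_bands` (scale up)")
  if (length(widths) > 1L && any(diff(widths) >= 0L))
    stop("widths must be strictly decreasing after the first hidden layer")
  if (utils::tail(widths, 1L) != 1L) stop("final width must be 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)")
  structure(list(input_bands = as.integer(input_bands), widths = widths,
                 dropout_rate = dropout_rate, activation = activation,
                 seed = as.integer(seed)),
            class = "deepfc_spec")
}

#' Training configuration for the deep regressors
#'
#' Defaults follow the tuned recipe for canopy-spectra regression: batch
#' size 4, Adam at learning rate 1e-4, RMSE loss with MAE as the tracked
#' metric, early stopping on validation RMSE.
#'
#' @param batch_size minibatch size (default 4).
#' @param learning_rate Adam step size (default 1e-4).
#' @param max_epochs epoch budget (default 500).
#' @param patience early-stopping epochs without validation improvement
#'   (default 50).
#' @param center_response learn on mean-centred responses and restore the
#'   offset at prediction (default TRUE; at learning rate 1e-4 an
#'   uncentred output head wastes thousands of steps reaching the trait
#'   mean).
#' @param standardize_input z-score the input bands (default FALSE: raw
#'   reflectance is the intended input path; never applied silently).
#' @param seed integer seed governing shuffling and dropout.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(batch_size = 4L, learning_rate = 1e-4,
                         max_epochs = 500L, patience = 50L,
                         center_response = TRUE,
                         standardize_input = FALSE, seed = 1L) {
  if (batch_size < 1L) stop("`batch_size` must be >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 optimizer = "adam", loss = "rmse", metric = "mae",
                 center_response = isTRUE(center_response),
                 standardize_input = isTRUE(standardize_input),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- layer primitives ----------------------------------------------------

.elu <- function(z) ifelse(z > 0, z, expm1(z))
.elu_grad <- function(z, a) ifelse(z > 0, 1, a + 1)

.glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# same-padding patch index table for a k x k kernel over a gr x gc grid
# (row-major band layout); out-of-grid taps point at the padding slot B+1.
.patch_index <- function(grid, k) {
  gr <- grid[1]; gc <- grid[2]; B <- gr * gc
  h <- (k - 1L) %/% 2L
  offs <- expand.grid(dr = -h:h, dc = -h:h)
  P <- matrix(B + 1L, nrow = B, ncol = k * k)
  b <- seq_len(B)
  r <- (b - 1L) %/% gc + 1L
  cc <- (b - 1L) %% gc + 1L
  for (t in seq_len(nrow(offs))) {
    rr <- r + offs$dr[t]; ccc <- cc + offs$dc[t]
    ok <- rr >= 1L & rr <= gr & ccc >= 1L & ccc <= gc
    P[ok, t] <- (rr[ok] - 1L) * gc + ccc[ok]
  }
  P
}

# ---- model construction --------------------------------------------------

.new_deep_model <- function(spec, layers, kind) {
  npar <- sum(vapply(layers, function(l) {
    if (l$type == "inception")
      sum(vapply(l$W, length, 0L)) + sum(vapply(l$b, length, 0L))
    else length(l$W) + length(l$b)
  }, numeric(1)))
  structure(list(spec = spec, layers = layers, kind = kind,
                 n_parameters = npar, offset = 0, trained = FALSE,
                 history = NULL),
            class = c(kind, "deep_model"))
}

#' Build an untrained Deep2D model
#'
#' @param spec a [deep2d_spec].
#' @return An untrained model of class \code{c("deep2d_model",
#'   "deep_model")}; \code{$n_parameters} reports the parameter count.
#' @export
build_deep2d <- function(spec = deep2d_spec()) {
  stopifnot(inherits(spec, "deep2d_spec"))
  .with_seed(spec$seed, {
    B <- spec$input_bands
    inc <- list(type = "inception", grid = spec$grid_shape,
                kernels = spec$branch_kernels, filters = spec$branch_filters,
                P = lapply(spec$branch_kernels, .patch_index,
                           grid = spec$grid_shape),
                W = list(), b = list())
    for (j in 1:3) {
      k2 <- spec$branch_kernels[j]^2
      f <- spec$branch_filters[j]
      inc$W[[j]] <- matrix(.glorot(k2, f, k2 * f), k2, f)
      inc$b[[j]] <- numeric(f)
    }
    dims <- c(B * sum(spec$branch_filters), spec$fc_widths, 1L)
    layers <- list(inc)
    for (d in seq_len(length(dims) - 1L)) {
      layers[[length(layers) + 1L]] <-
        list(type = "dense", act = "linear", dropout = 0,
             W = matrix(.glorot(dims[d], dims[d + 1L], dims[d] * dims[d + 1L]),
                        dims[d], dims[d + 1L]),
             b = numeric(dims[d + 1L]))
    }
    .new_deep_model(spec, layers, "deep2d_model")
  })
}

#' Build an untrained DeepFC model
#'
#' @param spec a [deepfc_spec].
#' @return An untrained model of class \code{c("deepfc_model",
#'   "deep_model")}.
#' @export
build_deepfc <- function(spec = deepfc_spec()) {
  stopifnot(inherits(spec, "deepfc_spec"))
  .with_seed(spec$seed, {
    dims <- c(spec$input_bands, spec$widths)
    layers <- list()
    for (d in seq_len(length(dims) - 1L)) {
      drop_here <- if (d <= 2L && dims[d + 1L] > 1L) spec$dropout_rate else 0
      act <- if (d < length(dims) - 1L) spec$activation else "linear"
      layers[[length(layers) + 1L]] <-
        list(type = "dense", act = act, dropout = drop_here,
             W = matrix(.glorot(dims[d], dims[d + 1L], dims[d] * dims[d + 1L]),
                        dims[d], dims[d + 1L]),
             b = numeric(dims[d + 1L]))
    }
    .new_deep_model(spec, layers, "deepfc_model")
  })
}

#' @export
print.deep_model <- function(x, ...) {
  cat(sprintf("<%s> %s, %d parameters, %s\n", class(x)[1],
              if (x$kind == "deep2d_model") "multi-scale convolutional regressor"
              else "expand-contract fully connected regressor",
              x$n_parameters,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---- forward / backward --------------------------------------------------

.forward_deep <- function(model, X, train = FALSE) {
  n <- nrow(X)
  cache <- vector("list", length(model$layers))
  A <- X
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "inception") {
      B <- prod(l$grid)
      Xz <- cbind(A, 0)
      outs <- vector("list", 3L)
      cc <- vector("list", 3L)
      for (j in 1:3) {
        k2 <- l$kernels[j]^2
        M <- matrix(Xz[, as.vector(l$P[[j]])], n * B, k2)
        Z <- M %*% l$W[[j]] + rep(l$b[[j]], each = n * B)
        Aj <- .elu(Z)
        cc[[j]] <- list(M = M, Z = Z, A = Aj)
        outs[[j]] <- matrix(Aj, n, B * l$filters[j])
      }
      cache[[li]] <- cc
      A <- do.call(cbind, outs)
    } else {
      Z <- A %*% l$W + rep(l$b, each = n)
      Anew <- if (l$act == "elu") .elu(Z) else Z
      mask <- NULL
      if (train && l$dropout > 0) {
        mask <- matrix(stats::rbinom(length(Anew), 1L, 1 - l$dropout) /
                         (1 - l$dropout), n, ncol(Anew))
        Anew <- Anew * mask
      }
      cache[[li]] <- list(A_in = A, Z = Z, mask = mask)
      A <- Anew
    }
  }
  list(out = as.vector(A), cache = cache)
}

.backward_deep <- function(model, fw, dout) {
  n <- length(dout)
  grads <- vector("list", length(model$layers))
  dA <- matrix(dout, n, 1L)
  for (li in rev(seq_along(model$layers))) {
    l <- model$layers[[li]]
    cc <- fw$cache[[li]]
    if (l$type == "dense") {
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      dZ <- if (l$act == "elu") dA * .elu_grad(cc$Z, .elu(cc$Z)) else dA
      grads[[li]] <- list(W = crossprod(cc$A_in, dZ), b = colSums(dZ))
      if (li > 1L) dA <- dZ %*% t(l$W)
    } else {
      # inception is the input layer: parameter grads only
      B <- prod(l$grid)
      gW <- gb <- vector("list", 3L)
      off <- 0L
      for (j in 1:3) {
        f <- l$filters[j]
        dAj <- dA[, off + seq_len(B * f), drop = FALSE]
        off <- off + B * f
        dAm <- matrix(dAj, n * B, f)
        dZ <- dAm * .elu_grad(cc[[j]]$Z, cc[[j]]$A)
        gW[[j]] <- crossprod(cc[[j]]$M, dZ)
        gb[[j]] <- colSums(dZ)
      }
      grads[[li]] <- list(W = gW, b = gb)
    }
  }
  grads
}

# ---- Adam training -------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(l) {
    zero <- function(x) if (is.list(x)) lapply(x, function(z) z * 0) else x * 0
    list(mW = zero(l$W), vW = zero(l$W), mb = zero(l$b), vb = zero(l$b))
  })
}

.adam_step <- function(layers, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (li in seq_along(layers)) {
    l <- layers[[li]]; g <- grads[[li]]; s <- state[[li]]
    if (is.list(l$W) && !is.matrix(l$W)) {
      for (j in seq_along(l$W)) {
        r <- upd(l$W[[j]], g$W[[j]], s$mW[[j]], s$vW[[j]])
        l$W[[j]] <- r$p; s$mW[[j]] <- r$m; s$vW[[j]] <- r$v
        r <- upd(l$b[[j]], g$b[[j]], s$mb[[j]], s$vb[[j]])
        l$b[[j]] <- r$p; s$mb[[j]] <- r$m; s$vb[[j]] <- r$v
      }
    } else {
      r <- upd(l$W, g$W, s$mW, s$vW)
      l$W <- r$p; s$mW <- r$m; s$vW <- r$v
      r <- upd(l$b, g$b, s$mb, s$vb)
      l$b <- r$p; s$mb <- r$m; s$vb <- r$v
    }
    layers[[li]] <- l; state[[li]] <- s
  }
  list(layers = layers, state = state)
}

#' Train a deep spectral regressor
#'
#' Minimizes the RMSE loss with Adam at the configured learning rate and
#' batch size, tracking RMSE and MAE on the calibration and validation
#' sets each epoch. The returned model carries the weights of the epoch
#' with minimal validation RMSE (early stopping with the configured
#' patience). With \code{max_epochs = 0} the model is returned exactly as
#' initialized.
#'
#' @param model an untrained model from [build_deep2d] or [build_deepfc].
#' @param X_cal,y_cal calibration spectra ([spectra_matrix] or matrix) and
#'   trait values.
#' @param X_val,y_val validation spectra and trait values (disjoint from
#'   calibration).
#' @param config a [train_config].
#' @return The trained model; \code{$history} holds the per-epoch
#'   data.frame (epoch, train_rmse, val_rmse, train_mae, val_mae) and
#'   \code{$best_epoch} the retained epoch.
#' @export
train_deep <- function(model, X_cal, y_cal, X_val, y_val,
                       config = train_config()) {
  stopifnot(inherits(model, "deep_model"), inherits(config, "train_config"))
  Xc <- .as_values(X_cal); Xv <- .as_values(X_val)
  if (inherits(X_cal, "spectra_matrix") && inherits(X_val, "spectra_matrix") &&
      length(intersect(X_cal$ids, X_val$ids)))
    stop("calibration and validation sample ids must be disjoint")
  if (length(y_cal) != nrow(Xc) || length(y_val) != nrow(Xv))
    stop("trait vectors must align with their spectra")
  if (config$max_epochs == 0L) {
    model$history <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                                val_rmse = numeric(0), train_mae = numeric(0),
                                val_mae = numeric(0))
    return(model)
  }
  if (config$standardize_input) {
    mu <- colMeans(Xc); sdv <- apply(Xc, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    model$input_scale <- list(mu = mu, sd = sdv)
    Xc <- sweep(sweep(Xc, 2L, mu), 2L, sdv, "/")
    Xv <- sweep(sweep(Xv, 2L, mu), 2L, sdv, "/")
  }
  offset <- if (config$center_response) mean(y_cal) else 0
  yc <- y_cal - offset; yv <- y_val - offset
  n <- nrow(Xc)
  .with_seed(config$seed, {
    layers <- model$layers
    state <- .adam_init(layers)
    best <- list(val = Inf, layers = layers, epoch = 0L)
    hist <- vector("list", config$max_epochs)
    t <- 0L
    tmp <- model
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        tmp$layers <- layers
        fw <- .forward_deep(tmp, Xc[idx, , drop = FALSE], train = TRUE)
        resid <- fw$out - yc[idx]
        loss <- sqrt(mean(resid^2))
        if (!is.finite(loss))
          stop("NaN/Inf training loss: try a smaller learning rate")
        dout <- if (loss > 0) resid / (length(idx) * loss) else resid * 0
        grads <- .backward_deep(tmp, fw, dout)
        t <- t + 1L
        st <- .adam_step(layers, grads, state, config$learning_rate, t)
        layers <- st$layers; state <- st$state
      }
      tmp$layers <- layers
      pc <- .forward_deep(tmp, Xc, train = FALSE)$out
      pv <- .forward_deep(tmp, Xv, train = FALSE)$out
      hist[[ep]] <- data.frame(epoch = ep,
                               train_rmse = sqrt(mean((pc - yc)^2)),
                               val_rmse = sqrt(mean((pv - yv)^2)),
                               train_mae = mean(abs(pc - yc)),
                               val_mae = mean(abs(pv - yv)))
      if (hist[[ep]]$val_rmse < best$val) {
        best <- list(val = hist[[ep]]$val_rmse, layers = layers, epoch = ep)
      } else if (ep - best$epoch >= config$patience) break
    }
    model$layers <- best$layers
    model$offset <- offset
    model$trained <- TRUE
    model$best_epoch <- best$epoch
    model$config <- config
    model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
    model
  })
}

#' Predict traits with a deep regressor
#'
#' Deterministic evaluation-mode forward pass (dropout disabled), one
#' scalar per sample.
#'
#' @param model a (trained or untrained) \code{deep_model}.
#' @param X a [spectra_matrix] or numeric matrix with the model's band
#'   count.
#' @return Numeric trait vector.
#' @export
predict_deep <- function(model, X) {
  stopifnot(inherits(model, "deep_model"))
  Xv <- .as_values(X)
  if (ncol(Xv) != model$spec$input_bands)
    stop("band count mismatch: model expects ", model$spec$input_bands,
         " bands, input has ", ncol(Xv))
  if (nrow(Xv) == 0L) return(numeric(0))
  if (!is.null(model$input_scale))
    Xv <- sweep(sweep(Xv, 2L, model$input_scale$mu), 2L,
                model$input_scale$sd, "/")
  .forward_deep(model, Xv, train = FALSE)$out + model$offset
}

#' @export
predict.deep_model <- function(object, newdata, ...) predict_deep(object, newdata)

#' Write a deep-model training history to CSV
#' @param model a trained \code{deep_model}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_history <- function(model, path) {
  stopifnot(inherits(model, "deep_model"))
  if (is.null(model$history)) stop("model has no training history")
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
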