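#' @name chemometric_models
#' @title Multivariate regression baselines
#'
#' @description Five classical chemometric regressors behind a uniform
#' fit/predict contract: partial least squares regression (PLSR), locally
#' weighted regression (LWR), multiple linear regression (MLR), a shallow
#' feed-forward artificial neural network (ANN, via \pkg{nnet}) and
#' epsilon-insensitive support vector regression (SVR, via \pkg{e1071}).
#' Every fit returns a classed S3 object storing its band axis; predict
#' methods reject inputs whose band axis differs.
NULL

.model_meta <- function(X, family, hyper) {
  list(family = family, hyper = hyper,
       wavelengths = if (inherits(X, "spectra_matrix")) X$wavelengths else
         seq_len(ncol(.as_values(X))),
       training_ids = if (inherits(X, "spectra_matrix")) X$ids else NULL)
}

.check_bands <- function(model, X) {
  Xv <- .as_values(X)
  if (ncol(Xv) != length(model$meta$wavelengths))
    stop("band axis mismatch: model expects ", length(model$meta$wavelengths),
         " bands, input has ", ncol(Xv))
  if (inherits(X, "spectra_matrix") &&
      max(abs(X$wavelengths - model$meta$wavelengths)) > 1e-8)
    stop("band axis mismatch: input wavelengths differ from the model's")
  Xv
}

#' @export
print.chemo_model <- function(x, ...) {
  cat(sprintf("<%s> %s model, %d bands, %d training samples\n",
              class(x)[1], x$meta$family, length(x$meta$wavelengths),
              length(x$fitted)))
  invisible(x)
}

# ---- PLSR ----------------------------------------------------------------

#' Partial least squares regression
#'
#' PLS1 via NIPALS: latent components chosen to maximize covariance between
#' X scores and the trait. With all components (full column space, well
#' conditioned X) the coefficients coincide with ordinary least squares.
#'
#' @param X a [spectra_matrix] or numeric matrix (rows = samples).
#' @param y numeric trait vector.
#' @param n_components number of latent components,
#'   \code{1 <= n_components <= min(n - 1, B)}.
#' @return A fitted model of class \code{c("plsr_model", "chemo_model")}
#'   with \code{$coef} and \code{$intercept}; prediction is linear.
#' @export
fit_plsr <- function(X, y, n_components = 10L) {
  Xv <- .as_values(X)
  if (length(y) != nrow(Xv)) stop("`y` must align with rows of `X`")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > min(nrow(Xv) - 1L, ncol(Xv)))
    stop("`n_components` must be in 1..min(n-1, B)")
  core <- .pls1_core(Xv, y, n_components)
  cf <- .pls1_coefs(core)
  obj <- structure(
    list(core = core, coef = cf$coef, intercept = cf$intercept,
         fitted = as.vector(Xv %*% cf$coef) + cf$intercept,
         meta = .model_meta(X, "PLSR", list(n_components = n_components))),
    class = c("plsr_model", "chemo_model"))
  obj
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  Xv <- .check_bands(object, newdata)
  if (nrow(Xv) == 0L) return(numeric(0))
  as.vector(Xv %*% object$coef) + object$intercept
}

# ---- MLR -----------------------------------------------------------------

#' Multiple linear regression
#'
#' Ordinary least squares of the trait on all bands. When the design is
#' rank-deficient (collinear bands, or more bands than samples) the
#' minimum-norm solution is taken through an SVD pseudo-inverse and the fit
#' is flagged, with a warning.
#'
#' @inheritParams fit_plsr
#' @return A fitted model of class \code{c("mlr_model", "chemo_model")}
#'   with \code{$coef}, \code{$intercept} and \code{$pseudo_inverse} flag.
#' @export
fit_mlr <- function(X, y) {
  Xv <- .as_values(X)
  if (length(y) != nrow(Xv)) stop("`y` must align with rows of `X`")
  n <- nrow(Xv); p <- ncol(Xv)
  xm <- colMeans(Xv); ym <- mean(y)
  Xc <- sweep(Xv, 2L, xm); yc <- y - ym
  qrX <- qr(Xc)
  pseudo <- FALSE
  if (n > p && qrX$rank == p) {
    b <- qr.coef(qrX, yc)
  } else {
    pseudo <- TRUE
    warning("rank-deficient design (n <= B or collinear bands): ",
            "using the minimum-norm pseudo-inverse solution")
    sv <- svd(Xc)
    tol <- max(dim(Xc)) * max(sv$d, 0) * .Machine$double.eps
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    b <- sv$v %*% (dinv * crossprod(sv$u, yc))
  }
  b <- as.vector(b)
  obj <- structure(
    list(coef = b, intercept = ym - sum(xm * b),
         pseudo_inverse = pseudo,
         fitted = as.vector(Xv %*% b) + ym - sum(xm * b),
         meta = .model_meta(X, "MLR", list())),
    class = c("mlr_model", "chemo_model"))
  obj
}

#' @export
predict.mlr_model <- function(object, newdata, ...) {
  Xv <- .check_bands(object, newdata)
  if (nrow(Xv) == 0L) return(numeric(0))
  as.vector(Xv %*% object$coef) + object$intercept
}

# ---- LWR -----------------------------------------------------------------

#' Locally weighted regression
#'
#' A lazy learner: queries are projected into a global PLS score space,
#' the nearest calibration samples are selected there, and a
#' distance-weighted local linear model in the scores predicts the query.
#' The score-space metric tames the collinearity of raw band space.
#'
#' @inheritParams fit_plsr
#' @param neighborhood neighbourhood size: a count, or a fraction of n if
#'   strictly between 0 and 1. Should be at least \code{n_components + 2}
#'   for a genuine local fit; smaller neighbourhoods (down to 1) fall back
#'   to a distance-weighted mean. Clipped to n with a warning if larger.
#' @param n_components dimension of the PLS score space.
#' @param weights \code{"tricube"} distance weights (default) or
#'   \code{"uniform"}.
#' @return A fitted model of class \code{c("lwr_model", "chemo_model")}.
#' @export
fit_lwr <- function(X, y, neighborhood = 30, n_components = 5L,
                    weights = c("tricube", "uniform")) {
  weights <- match.arg(weights)
  Xv <- .as_values(X)
  n <- nrow(Xv)
  if (length(y) != nrow(Xv)) stop("`y` must align with rows of `X`")
  if (neighborhood < 1) neighborhood <- max(1, round(neighborhood * n))
  neighborhood <- as.integer(neighborhood)
  n_components <- as.integer(min(n_components, n - 1L, ncol(Xv)))
  if (neighborhood > n) {
    warning("`neighborhood` larger than n; clipped to ", n)
    neighborhood <- n
  }
  core <- .pls1_core(Xv, y, n_components)
  obj <- structure(
    list(core = core, scores = .pls1_scores(core, Xv), y = y,
         neighborhood = neighborhood, weights = weights,
         fitted = NULL,
         meta = .model_meta(X, "LWR",
                            list(neighborhood = neighborhood,
                                 n_components = n_components,
                                 weights = weights))),
    class = c("lwr_model", "chemo_model"))
  obj$fitted <- predict(obj, Xv)
  obj
}

#' @export
predict.lwr_model <- function(object, newdata, ...) {
  Xv <- if (is.matrix(newdata) || inherits(newdata, "spectra_matrix"))
    .check_bands(object, newdata) else matrix(newdata, nrow = 1L)
  if (nrow(Xv) == 0L) return(numeric(0))
  Tq <- .pls1_scores(object$core, Xv)
  Tt <- object$scores
  k <- object$neighborhood
  vapply(seq_len(nrow(Tq)), function(i) {
    d <- sqrt(colSums((t(Tt) - Tq[i, ])^2))
    nb <- order(d)[seq_len(k)]
    w <- if (object$weights == "uniform") rep(1, k) else {
      dmax <- max(d[nb])
      if (dmax == 0) rep(1, k) else (1 - pmin(d[nb] / dmax, 1)^3)^3 + 1e-9
    }
    Z <- cbind(1, Tt[nb, , drop = FALSE])
    if (k >= ncol(Z) + 1L) {
      fit <- stats::lm.wfit(Z, object$y[nb], w)
      beta <- fit$coefficients
      if (!anyNA(beta))
        return(sum(beta * c(1, Tq[i, ])))
    }
    sum(w * object$y[nb]) / sum(w)  # degenerate neighbourhood fallback
  }, numeric(1))
}

# ---- ANN -----------------------------------------------------------------

#' Shallow neural network regression
#'
#' Single-hidden-layer feed-forward regressor (logistic hidden units,
#' linear output) fitted by BFGS through \pkg{nnet}. Initial weights are
#' drawn from the stated seed, so fits are deterministic; \code{epochs = 0}
#' returns the untrained initialization.
#'
#' @inheritParams fit_plsr
#' @param hidden hidden layer size (default 32).
#' @param epochs maximum optimizer iterations (default 200).
#' @param decay weight decay (default 0).
#' @param seed integer seed for the weight initialization.
#' @return A fitted model of class \code{c("ann_model", "chemo_model")}
#'   with \code{$converged}.
#' @export
fit_ann <- function(X, y, hidden = 32L, epochs = 200L, decay = 0,
                    seed = 1L) {
  Xv <- .as_values(X)
  if (length(y) != nrow(Xv)) stop("`y` must align with rows of `X`")
  hidden <- as.integer(hidden); epochs <- as.integer(epochs)
  p <- ncol(Xv)
  nw <- (p + 1L) * hidden + (hidden + 1L)
  w0 <- .with_seed(seed, stats::runif(nw, -0.7, 0.7))
  fit <- nnet::nnet(Xv, y, size = hidden, linout = TRUE, maxit = epochs,
                    decay = decay, Wts = w0, trace = FALSE,
                    MaxNWts = nw + 1L)
  if (epochs == 0L) fit$wts <- w0  # contract: no training performed
  obj <- structure(
    list(net = fit, converged = isTRUE(fit$convergence == 0),
         fitted = NULL,
         meta = .model_meta(X, "ANN",
                            list(hidden = hidden, epochs = epochs,
                                 decay = decay, seed = seed))),
    class = c("ann_model", "chemo_model"))
  obj$fitted <- predict(obj, Xv)
  obj
}

#' @export
predict.ann_model <- function(object, newdata, ...) {
  Xv <- .check_bands(object, newdata)
  if (nrow(Xv) == 0L) return(numeric(0))
  as.vector(predict(object$net, Xv))
}

# ---- SVR -----------------------------------------------------------------

#' Support vector regression
#'
#' Epsilon-insensitive SVR through \pkg{e1071} (libsvm). Inputs are not
#' rescaled internally: reflectance bands share a common scale already, and
#' leaving them untouched keeps duplicate-row predictions exactly equal.
#'
#' @inheritParams fit_plsr
#' @param kernel libsvm kernel (default \code{"radial"}).
#' @param cost constraint-violation cost C (> 0).
#' @param epsilon insensitive-tube half-width (>= 0).
#' @param gamma kernel coefficient; default \code{1/B}.
#' @return A fitted model of class \code{c("svr_model", "chemo_model")}
#'   with \code{$n_support}.
#' @export
fit_svr <- function(X, y, kernel = "radial", cost = 1, epsilon = 0.1,
                    gamma = NULL) {
  Xv <- .as_values(X)
  if (length(y) != nrow(Xv)) stop("`y` must align with rows of `X`")
  if (cost <= 0) stop("`cost` must be positive")
  if (epsilon < 0) stop("`epsilon` must be nonnegative")
  if (is.null(gamma)) gamma <- 1 / ncol(Xv)
  fit <- e1071::svm(Xv, y, type = "eps-regression", kernel = kernel,
                    cost = cost, epsilon = epsilon, gamma = gamma,
                    scale = FALSE, fitted = FALSE)
  obj <- structure(
    list(svm = fit, n_support = fit$tot.nSV, fitted = NULL,
         meta = .model_meta(X, "SVR",
                            list(kernel = kernel, cost = cost,
                                 epsilon = epsilon, gamma = gamma))),
    class = c("svr_model", "chemo_model"))
  obj$fitted <- predict(obj, Xv)
  obj
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  Xv <- .check_bands(object, newdata)
  if (nrow(Xv) == 0L) return(numeric(0))
  if (object$n_support == 0L) {
    # all residuals inside the insensitive tube: the decision function
    # degenerates to the constant -rho
    return(rep(-object$svm$rho, nrow(Xv)))
  }
  as.vector(predict(object$svm, Xv))
}

# ---- serialization -------------------------------------------------------

#' Export a fitted model description to JSON
#'
#' Family, hyperparameters and (for linear families) the coefficient
#' arrays. Opaque fitted state of kernel/neural models is not persisted.
#'
#' @param model a fitted \code{chemo_model}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "chemo_model"))
  out <- list(family = model$meta$family, hyperparameters = model$meta$hyper,
              wavelengths = model$meta$wavelengths)
  if (!is.null(model$coef)) {
    out$coef <- model$coef
    out$intercept <- model$intercept
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
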