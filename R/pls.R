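# PLS1 (single-response partial least squares) by the NIPALS deflation
# scheme, used by fit_plsr, fit_lwr's score space and CARS. X and y are
# centred internally; coefficients are returned on the original scale.

.pls1_core <- function(X, y, ncomp, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xr <- sweep(X, 2L, xm); yr <- y - ym
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    tt <- Xr %*% w
    t2 <- sum(tt^2)
    if (t2 < tol) break
    pk <- crossprod(Xr, tt) / t2
    qk <- sum(yr * tt) / t2
    Xr <- Xr - tt %*% t(pk)
    yr <- yr - qk * tt
    W[, k] <- w; P[, k] <- pk; qv[k] <- qk
    a <- k
  }
  if (a == 0L)
    stop("degenerate data: X has no variance correlated with y")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  qv <- qv[seq_len(a)]
  # weights in the original X basis: R = W (P'W)^-1 ; P'W is upper triangular
  R <- W %*% backsolve(t(P) %*% W, diag(a))
  list(W = W, P = P, q = qv, R = R, xm = xm, ym = ym, ncomp = a)
}

.pls1_coefs <- function(fit, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  Rk <- fit$W[, seq_len(ncomp), drop = FALSE] %*%
    backsolve(t(fit$P[, seq_len(ncomp), drop = FALSE]) %*%
                fit$W[, seq_len(ncomp), drop = FALSE], diag(ncomp))
  b <- as.vector(Rk %*% fit$q[seq_len(ncomp)])
  list(coef = b, intercept = fit$ym - sum(fit$xm * b))
}

.pls1_scores <- function(fit, X) {
  sweep(as.matrix(X), 2L, fit$xm) %*% fit$R
}

# K-fold cross-validated RMSE of PLS1 per component count. Folds are
# assigned deterministically by cycling over a seeded permutation.
.pls1_cv <- function(X, y, folds = 5L, max_comp = 10L, seed = 1L) {
  n <- nrow(X)
  folds <- min(folds, n)
  perm <- .with_seed(seed, sample.int(n))
  fold_id <- rep_len(seq_len(folds), n)[order(perm)]
  max_comp <- min(max_comp, n - ceiling(n / folds) - 1L, ncol(X))
  max_comp <- max(max_comp, 1L)
  sse <- numeric(max_comp)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    if (!any(te) || sum(tr) < 2L) next
    fit <- .pls1_core(X[tr, , drop = FALSE], y[tr], max_comp)
    for (k in seq_len(max_comp)) {
      cf <- .pls1_coefs(fit, k)
      pred <- as.vector(X[te, , drop = FALSE] %*% cf$coef) + cf$intercept
      sse[k] <- sse[k] + sum((pred - y[te])^2)
    }
  }
  rmsecv <- sqrt(sse / n)
  list(rmsecv = rmsecv, best = which.min(rmsecv))
}
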