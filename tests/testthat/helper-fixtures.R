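# Shared fixture builders; everything is generated in code, nothing stored.

tiny_spectra <- function(n = 6, b = 16, seed = 1) {
  set.seed(seed)
  spectra_matrix(matrix(runif(n * b, 0.1, 0.6), n, b),
                 seq(400, 1000, length.out = b))
}

# independent Kennard-Stone oracle: literal max-min rule with double loops
ks_brute_force <- function(X, m) {
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  best <- NULL; bd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < m) {
    cand <- setdiff(seq_len(n), sel)
    mind <- vapply(cand, function(cc) min(D[cc, sel]), numeric(1))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

# independent per-pixel SAM oracle using the scalar primitive
sam_brute_force <- function(cube, em, threshold) {
  d <- dim(cube$data)
  mask <- matrix(FALSE, d[1], d[2])
  for (l in seq_len(d[1])) for (s in seq_len(d[2])) {
    px <- cube$data[l, s, ]
    angs <- vapply(seq_len(nrow(em$spectra)), function(k)
      spectral_angle(px, em$spectra[k, ]), numeric(1))
    ap <- min(angs[em$labels == "plant"])
    ok <- ap < threshold
    if (any(em$labels == "background"))
      ok <- ok && ap < min(angs[em$labels == "background"])
    mask[l, s] <- ok
  }
  mask
}
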