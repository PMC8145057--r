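# independent brute-force oracle: plain enumeration with its own LDA and
# leave-one-out code (held-out accuracy; held-out mean signed margin on
# globally z-scored features as the tie-break)
oracle_search <- function(X, y01, k_max, shrinkage = 0.1) {
  ids <- colnames(X)
  fit0 <- function(A, yy) {
    A0 <- A[yy == 0, , drop = FALSE]; A1 <- A[yy == 1, , drop = FALSE]
    m0 <- colMeans(A0); m1 <- colMeans(A1)
    S <- ((nrow(A0) - 1) * cov(A0) + (nrow(A1) - 1) * cov(A1)) /
      (nrow(A) - 2)
    S[is.na(S)] <- 0
    S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(A))
    diag(S) <- diag(S) + 1e-10 * (mean(diag(S)) + 1e-12)
    w <- solve(S, m1 - m0)
    list(w = w, b = -sum(w * (m0 + m1)) / 2)
  }
  Z <- scale(X)
  loo <- function(cols) {
    res <- vapply(seq_len(nrow(Z)), function(i) {
      f <- fit0(Z[-i, cols, drop = FALSE], y01[-i])
      s <- sum(Z[i, cols] * f$w) + f$b
      c(ok = (s > 0) == (y01[i] == 1),
        marg = (if (y01[i] == 1) s else -s) / sqrt(sum(f$w^2)))
    }, numeric(2))
    list(acc = mean(res["ok", ]), mar = mean(res["marg", ]))
  }
  best <- NULL
  for (k in seq_len(k_max)) {
    sets <- combn(length(ids), k)
    for (j in seq_len(ncol(sets))) {
      cols <- sets[, j]
      r <- loo(cols)
      cand <- list(cols = cols, acc = r$acc, mar = r$mar)
      if (is.null(best) || cand$acc > best$acc ||
          (cand$acc == best$acc && cand$mar > best$mar)) {
        best <- cand
      }
    }
  }
  list(peak_ids = ids[sort(best$cols)], acc = best$acc, mar = best$mar)
}
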