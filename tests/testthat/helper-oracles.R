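# independent straight-line oracles: explicit loops over the defining
# formulas, sharing no code with the package internals

brute_attention <- function(Q, K, V) {
  n <- nrow(Q); m <- nrow(K)
  W <- matrix(0, n, m)
  for (i in seq_len(n)) {
    logit <- numeric(m)
    for (j in seq_len(m)) logit[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(Q))
    e <- exp(logit)
    W[i, ] <- e / sum(e)
  }
  list(output = W %*% V, weights = W)
}

brute_conv <- function(X, params) {
  n <- nrow(X); d <- ncol(X)
  out <- NULL
  for (kr in params$kernels) {
    w <- kr$w
    left <- (w - 1) %/% 2
    O <- matrix(0, n, nrow(kr$W))
    for (t in seq_len(n)) {
      xwin <- numeric(w * d)
      for (o in 0:(w - 1)) {
        src <- t + o - left
        if (src >= 1 && src <= n) xwin[(o * d + 1):((o + 1) * d)] <- X[src, ]
      }
      for (f in seq_len(nrow(kr$W)))
        O[t, f] <- max(sum(kr$W[f, ] * xwin) + kr$b[f], 0)
    }
    out <- cbind(out, O)
  }
  out
}

brute_routing <- function(u_hat, r) {
  N <- dim(u_hat)[1]; J <- dim(u_hat)[2]; dp <- dim(u_hat)[3]
  z <- matrix(0, N, J)
  for (t in seq_len(r)) {
    cmat <- matrix(0, N, J)
    for (i in seq_len(N)) cmat[i, ] <- exp(z[i, ]) / sum(exp(z[i, ]))
    v <- matrix(0, J, dp)
    for (j in seq_len(J)) {
      s <- numeric(dp)
      for (i in seq_len(N)) s <- s + cmat[i, j] * u_hat[i, j, ]
      nrm2 <- sum(s^2)
      v[j, ] <- (nrm2 / (1 + nrm2)) * s / sqrt(nrm2 + 1e-8)
    }
    if (t < r) {
      for (i in seq_len(N)) for (j in seq_len(J))
        z[i, j] <- z[i, j] + sum(u_hat[i, j, ] * v[j, ])
    }
  }
  list(v = v, c = cmat)
}
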