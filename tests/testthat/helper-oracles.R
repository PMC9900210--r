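# Independent brute-force oracles.  Everything here is a deliberately naive
# loop/enumeration implementation, kept free of the package's vectorized or
# compiled code paths so the two can be compared.

rmat <- function(L, C, sd = 1) matrix(rnorm(L * C, sd = sd), L, C)

oracle_mse <- function(p, y) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - y[i])^2
  s / length(p)
}

oracle_rwing <- function(x, w, r, epsilon) {
  C <- w - w * log(1 + (w - r) / epsilon)
  vapply(x, function(xi) {
    a <- abs(xi)
    if (a < r) 0
    else if (a < w) w * log(1 + (a - r) / epsilon)
    else a - C
  }, numeric(1))
}

oracle_ci <- function(preds, labels) {
  num <- 0; Z <- 0
  n <- length(preds)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] > labels[j]) {
      Z <- Z + 1
      d <- preds[i] - preds[j]
      num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
    }
  }
  num / Z
}

# rm2 via lm(): r2 with intercept from the standard regression, r02 from the
# through-origin slope k = sum(y*f)/sum(f^2)
oracle_rm2 <- function(preds, labels) {
  r2 <- summary(lm(labels ~ preds))$r.squared
  k <- sum(labels * preds) / sum(preds^2)
  r02 <- 1 - sum((labels - k * preds)^2) / sum((labels - mean(labels))^2)
  r2 * (1 - sqrt(max(r2 - r02, 0)))
}

# AUPR by explicit sweep over every distinct score threshold
oracle_aupr <- function(scores, pos) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(pos)
  prec <- rec <- numeric(length(th))
  for (t in seq_along(th)) {
    sel <- scores >= th[t]
    prec[t] <- sum(pos & sel) / sum(sel)
    rec[t] <- sum(pos & sel) / P
  }
  sum(diff(c(0, rec)) * prec)
}

oracle_response <- function(Fp, K) {
  L <- nrow(Fp); C <- ncol(Fp); k <- nrow(K); p <- k %/% 2
  s <- numeric(L)
  for (i in seq_len(L)) {
    acc <- 0
    for (m in seq_len(k)) for (n in seq_len(C)) {
      row <- i + (m - 1) - p
      if (row >= 1 && row <= L) acc <- acc + K[m, n] * Fp[row, n]
    }
    s[i] <- acc
  }
  s
}

oracle_softmax_len <- function(Z) {
  Y <- Z
  for (c in seq_len(ncol(Z))) {
    e <- exp(Z[, c] - max(Z[, c]))
    Y[, c] <- e / sum(e)
  }
  Y
}

oracle_self_enhance <- function(X, W1, Wm) {
  (X %*% W1) * oracle_softmax_len((X %*% Wm) / ncol(X))
}

oracle_cross_attend <- function(Xp, Xd, Wm1, Wm2) {
  Xm <- rbind(Xp, Xd)
  fa <- oracle_softmax_len((Xm %*% Wm1) / ncol(Xm))
  Xm + t(t(Xm %*% Wm1) %*% Wm2) * fa
}

oracle_conv2d <- function(X, W, b) {
  L <- nrow(X); C <- ncol(X); k <- nrow(W); p <- k %/% 2
  out <- matrix(b, L, C)
  for (i in seq_len(L)) for (c in seq_len(C))
    for (u in seq_len(k)) for (v in seq_len(k)) {
      ri <- i + (u - 1) - p; ci <- c + (v - 1) - p
      if (ri >= 1 && ri <= L && ci >= 1 && ci <= C)
        out[i, c] <- out[i, c] + W[u, v] * X[ri, ci]
    }
  out
}

oracle_conv1d_group <- function(X, W, b, k, groups) {
  L <- nrow(X); C <- ncol(X); Cg <- C / groups; p <- k %/% 2
  out <- matrix(0, L, C)
  for (co in seq_len(C)) {
    g <- ceiling(co / Cg)
    chans <- (g - 1) * Cg + seq_len(Cg)
    for (i in seq_len(L)) {
      acc <- b[co]
      for (j in seq_len(k)) for (ci in seq_along(chans)) {
        ri <- i + (j - 1) - p
        if (ri >= 1 && ri <= L)
          acc <- acc + W[(j - 1) * Cg + ci, co] * X[ri, chans[ci]]
      }
      out[i, co] <- acc
    }
  }
  out
}

oracle_fuse <- function(X1, X2, prm) {
  gate <- oracle_conv2d(X1, prm$gate$W1, prm$gate$b) +
    oracle_conv2d(X2, prm$gate$W2, 0)
  Watt <- 1 / (1 + exp(-gate))
  fc <- function(X, p) {
    h <- X %*% p$W
    for (c in seq_len(ncol(h))) h[, c] <- h[, c] + p$b[c]
    h * (h > 0)
  }
  fc(X1, prm$fc1_a) * Watt + X1 + fc(X2, prm$fc1_b) * (1 - Watt) + X2
}

oracle_merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[i, 1] <= out[last, 2]) out[last, 2] <- max(out[last, 2], iv[i, 2])
    else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}
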