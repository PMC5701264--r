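# Independent reference implementations used as oracles. These deliberately
# avoid the package's covariance-kernel code path.

# Classical NIPALS PLS2 on (already standardized) matrices; returns the
# coefficient matrix for each number of factors 1..fmax.
nipals_pls2 <- function(X, Y, fmax, tol = 1e-24, max_inner = 2000L) {
  I <- ncol(X); J <- ncol(Y)
  W <- matrix(0, I, fmax); P <- matrix(0, I, fmax); C <- matrix(0, J, fmax)
  Xd <- X; Yd <- Y
  for (f in seq_len(fmax)) {
    u <- Yd[, which.max(colSums(Yd^2))]
    for (it in seq_len(max_inner)) {
      w <- crossprod(Xd, u); w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      cc <- crossprod(Yd, tt) / sum(tt^2)
      un <- Yd %*% cc / sum(cc^2)
      if (sum((un - u)^2) < tol * sum(u^2)) { u <- un; break }
      u <- un
    }
    p <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(p)
    Yd <- Yd - tt %*% t(cc)
    W[, f] <- w; P[, f] <- p; C[, f] <- cc
  }
  lapply(seq_len(fmax), function(f) {
    Wf <- W[, 1:f, drop = FALSE]; Pf <- P[, 1:f, drop = FALSE]
    Cf <- C[, 1:f, drop = FALSE]
    Wf %*% solve(crossprod(Pf, Wf), t(Cf))
  })
}

# Triple-loop observation-mode contraction (brute force).
contract_obs_loop <- function(x, y) {
  dx <- dim(x); dy <- dim(y)
  xm <- x; dim(xm) <- c(dx[1], prod(dx[-1]))
  ym <- y; dim(ym) <- c(dy[1], prod(dy[-1]))
  out <- matrix(0, ncol(xm), ncol(ym))
  for (i in seq_len(ncol(xm)))
    for (j in seq_len(ncol(ym)))
      for (l in seq_len(nrow(xm)))
        out[i, j] <- out[i, j] + xm[l, i] * ym[l, j]
  array(out, c(dx[-1], dy[-1]))
}

# Explicit lambda^age-weighted mean/std from stored raw epoch batches.
# `batches` is a list of N_t x shape arrays; age 0 = newest batch.
weighted_moments_oracle <- function(batches, lambda) {
  nb <- length(batches)
  wsum <- 0; s <- 0; ss <- 0
  for (k in seq_len(nb)) {
    b <- batches[[k]]
    dim(b) <- c(dim(b)[1], prod(dim(b)[-1]))
    w <- lambda^(nb - k)
    wsum <- wsum + w * nrow(b)
    s <- s + w * colSums(b)
    ss <- ss + w * colSums(b^2)
  }
  list(mean = s / wsum, std = sqrt((ss - s^2 / wsum) / (wsum - 1)))
}

# Standardize train/test with pooled moments of `x` (matrix view).
pool_standardize <- function(a) {
  m <- a; dim(m) <- c(dim(a)[1], prod(dim(a)[-1]))
  scale(m)
}

# Split an N x ... tensor into k consecutive batches along the first mode.
split_batches <- function(a, k) {
  n <- dim(a)[1]
  idx <- split(seq_len(n), rep(seq_len(k), each = n / k))
  lapply(idx, function(i) {
    out <- a
    m <- a; dim(m) <- c(n, prod(dim(a)[-1]))
    m <- m[i, , drop = FALSE]
    array(m, c(length(i), dim(a)[-1]))
  })
}

# Stream a spec end-to-end with given lambda/gamma; returns final state, rv,
# trace (thin wrapper used by several tests).
run_stream <- function(spec, lambda, gamma, f_max, error = "mse", ...) {
  truth <- make_truth(spec)
  batches <- gen_batches(spec, truth)
  st <- rewnpls_init(spec$x_shape, spec$y_shape, lambda = lambda, f_max = f_max)
  rv <- rv_init(f_max, gamma = gamma, error = error)
  out <- decode_stream(st, rv, batches, ...)
  out$truth <- truth
  out$batches <- batches
  out
}
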