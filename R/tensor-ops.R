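#' Multilinear primitives
#'
#' Low-level tensor operations shared by all estimator code: contraction over
#' the observation mode, mode unfolding/folding under a fixed vectorization
#' convention, and best rank-one PARAFAC approximation by alternating least
#' squares (ALS).
#'
#' Vectorization convention: within any index group the FIRST listed mode
#' varies fastest. This coincides with R's native column-major array layout,
#' so `as.vector()` of an array is its canonical vectorization and all modules
#' can move between tensor and matricized views without copying semantics.
#'
#' @name tensor-ops
#' @keywords internal
NULL

#' Contract two tensors over their shared observation mode
#'
#' Computes the mode-1 (observation) tensor product of `x` and `y`: the result
#' at index `(i..., j...)` is `sum_l x[l, i...] * y[l, j...]`. This is the raw
#' cross-product accumulator from which covariance tensors are built; for
#' `contract_obs(x, x)` it is the (uncentered) Gram tensor.
#'
#' @param x Numeric array, first mode indexes observations (`N x I1 x ... x In`).
#' @param y Numeric array with the same first-mode size (`N x J1 x ... x Jm`).
#' @return Numeric array of shape `I1 x ... x In x J1 x ... x Jm`. For
#'   order-1 inputs on both sides this is a plain matrix.
#' @examples
#' x <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
#' y <- matrix(rnorm(3 * 2), 3, 2)
#' cxy <- contract_obs(x, y) # 2 x 2 x 2
#' @export
contract_obs <- function(x, y) {
  x <- as_tensor(x)
  y <- as_tensor(y)
  dx <- dim(x)
  dy <- dim(y)
  if (dx[1L] != dy[1L]) {
    stop("observation (first) modes differ: ", dx[1L], " vs ", dy[1L])
  }
  xm <- matricize_obs(x)
  ym <- matricize_obs(y)
  out <- crossprod(xm, ym)
  array(out, c(dx[-1L], dy[-1L]))
}

#' Unfold a tensor into a matrix
#'
#' Bijectively reindexes a tensor into a matrix whose rows enumerate
#' `row_modes` and whose columns enumerate `col_modes`. Within each group the
#' first listed mode varies fastest. `fold()` inverts the operation.
#'
#' @param a Numeric array.
#' @param row_modes Integer vector of mode indices mapped to rows.
#' @param col_modes Integer vector of mode indices mapped to columns.
#'   Together with `row_modes` this must be a permutation of `1:n_modes`.
#' @return A matrix of shape `prod(dim[row_modes]) x prod(dim[col_modes])`.
#' @examples
#' a <- array(1:24, c(2, 3, 4))
#' m <- unfold(a, row_modes = c(1, 2), col_modes = 3) # 6 x 4
#' all.equal(fold(m, dim(a), c(1, 2), 3), a)
#' @export
unfold <- function(a, row_modes, col_modes) {
  a <- as_tensor(a)
  d <- dim(a)
  k <- length(d)
  modes <- c(row_modes, col_modes)
  if (length(modes) != k || anyDuplicated(modes) || !setequal(modes, seq_len(k))) {
    stop("row_modes and col_modes must partition 1:", k)
  }
  ap <- aperm(a, modes)
  dim(ap) <- c(prod(d[row_modes]), prod(d[col_modes]))
  ap
}

#' @rdname unfold
#' @param m Matrix produced by `unfold()`.
#' @param shape Mode sizes of the original tensor.
#' @export
fold <- function(m, shape, row_modes, col_modes) {
  modes <- c(row_modes, col_modes)
  k <- length(shape)
  if (length(modes) != k || !setequal(modes, seq_len(k))) {
    stop("row_modes and col_modes must partition 1:", k)
  }
  dim(m) <- shape[modes]
  aperm(m, order(modes))
}

#' Best rank-one PARAFAC approximation
#'
#' Finds unit vectors `v1, ..., vK` (split into `n_x_modes` input-side
#' projectors and the remaining output-side loadings) maximizing the inner
#' product of `C` with their outer product, by alternating least squares.
#' For an order-2 tensor (a matrix) this is the dominant singular pair.
#'
#' The ALS objective (the `scale`) is non-decreasing over sweeps; iteration
#' stops when its relative change falls below `tol` or after `max_iter`
#' sweeps. Cold start uses the leading left singular vector of each
#' single-mode unfolding; a warm start can be supplied as a list of vectors.
#'
#' Sign convention: after convergence every input-side vector, and all but
#' the last output-side vector, has a nonnegative first nonzero entry; the
#' last output-side vector absorbs the residual sign so that `scale >= 0`.
#'
#' @param C Numeric array of order `n + m` (input modes first).
#' @param n_x_modes Number of leading modes belonging to the input side.
#' @param init Optional warm start: list of numeric vectors, one per mode.
#' @param tol Relative-objective-change stopping tolerance.
#' @param max_iter Maximum number of ALS sweeps.
#' @return An object of class `rank_one_factor`: list with `x_vectors`,
#'   `y_vectors`, `scale`, `degenerate`, `iterations`, `objective_trace`.
#' @examples
#' a <- c(3, 4) / 5; b <- c(1, 0, 0); C <- 2 * outer(a, b)
#' f <- rank_one_parafac(C, n_x_modes = 1)
#' f$scale # 2
#' @export
rank_one_parafac <- function(C, n_x_modes, init = NULL, tol = 1e-9,
                             max_iter = 100L) {
  C <- as_tensor(C)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (!all(is.finite(C))) stop("C must be finite")
  d <- dim(C)
  k <- length(d)
  if (n_x_modes < 1L || n_x_modes >= k + 1L) stop("invalid n_x_modes")

  if (all(C == 0)) {
    vecs <- lapply(d, function(s) c(1, numeric(s - 1L)))
    return(new_rank_one_factor(vecs, n_x_modes, scale = 0,
                               degenerate = TRUE, iterations = 0L,
                               objective_trace = numeric(0)))
  }

  vs <- if (!is.null(init)) {
    if (length(init) != k) stop("init must supply one vector per mode")
    mapply(function(v, s) {
      if (length(v) != s) stop("init vector length mismatch")
      n <- sqrt(sum(v^2))
      if (n == 0) c(1, numeric(s - 1L)) else v / n
    }, init, d, SIMPLIFY = FALSE)
  } else {
    lapply(seq_len(k), function(mode) {
      m <- unfold(C, mode, setdiff(seq_len(k), mode))
      svd(m, nu = 1L, nv = 0L)$u[, 1L]
    })
  }

  obj <- -Inf
  trace <- numeric(0)
  iters <- 0L
  for (sweep in seq_len(max_iter)) {
    iters <- sweep
    for (mode in seq_len(k)) {
      g <- contract_all_but(C, vs, mode)
      nrm <- sqrt(sum(g^2))
      if (nrm == 0) {
        # degenerate direction: keep previous vector
        next
      }
      vs[[mode]] <- g / nrm
    }
    new_obj <- sum(contract_all_but(C, vs, k) * vs[[k]])
    trace <- c(trace, new_obj)
    if (is.finite(obj) && abs(new_obj - obj) <= tol * max(abs(new_obj), 1e-300)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }

  # canonical signs: flip each vector except the last y-vector; the last
  # vector absorbs the accumulated sign so scale stays >= 0
  sign_acc <- 1
  for (mode in seq_len(k - 1L)) {
    s <- first_nonzero_sign(vs[[mode]])
    if (s < 0) {
      vs[[mode]] <- -vs[[mode]]
      sign_acc <- -sign_acc
    }
  }
  if (obj < 0) {
    sign_acc <- -sign_acc
    obj <- -obj
  }
  if (sign_acc < 0) vs[[k]] <- -vs[[k]]

  new_rank_one_factor(vs, n_x_modes, scale = obj, degenerate = FALSE,
                      iterations = iters, objective_trace = trace)
}

new_rank_one_factor <- function(vectors, n_x_modes, scale, degenerate,
                                iterations, objective_trace) {
  structure(
    list(
      x_vectors = vectors[seq_len(n_x_modes)],
      y_vectors = vectors[-seq_len(n_x_modes)],
      scale = scale,
      degenerate = degenerate,
      iterations = iterations,
      objective_trace = objective_trace
    ),
    class = "rank_one_factor"
  )
}

#' Reconstruct the rank-one tensor of a factor
#' @param f A `rank_one_factor`.
#' @return Numeric array `scale * x1 o ... o xn o y1 o ... o ym`.
#' @export
compose_rank_one <- function(f) {
  vecs <- c(f$x_vectors, f$y_vectors)
  out <- f$scale
  for (v in vecs) out <- outer(out, v)
  drop_first_unit(out)
}

# contract C with vs[[j]] for all modes j != mode; returns vector over `mode`
contract_all_but <- function(C, vs, mode) {
  d <- dim(C)
  k <- length(d)
  # move `mode` first, then fold in the remaining modes one matrix product
  # at a time (last mode first keeps indices stable)
  g <- aperm(C, c(mode, setdiff(seq_len(k), mode)))
  rest <- setdiff(seq_len(k), mode)
  cur_dim <- c(d[mode], d[rest])
  for (j in rev(seq_along(rest))) {
    dim(g) <- c(prod(cur_dim[seq_len(length(cur_dim) - 1L)]),
                cur_dim[length(cur_dim)])
    g <- g %*% vs[[rest[j]]]
    cur_dim <- cur_dim[-length(cur_dim)]
  }
  as.vector(g)
}

first_nonzero_sign <- function(v) {
  nz <- which(v != 0)
  if (length(nz) == 0L) 1 else sign(v[nz[1L]])
}

# ---- small shared helpers ----

as_tensor <- function(a) {
  if (is.null(dim(a))) dim(a) <- length(a)
  storage.mode(a) <- "double"
  a
}

# N x I1 x ... x In -> N x prod(I) matrix; under the first-mode-fastest
# convention this is a plain column-major reshape
matricize_obs <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1L], prod(d[-1L]))
  a
}

# inverse of matricize_obs
tensorize_obs <- function(m, coord_shape) {
  dim(m) <- c(nrow(m), coord_shape)
  m
}

drop_first_unit <- function(a) {
  d <- dim(a)
  if (!is.null(d) && length(d) > 1L && d[1L] == 1L) {
    dim(a) <- d[-1L]
  }
  a
}
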