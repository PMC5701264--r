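#' Exponentially weighted running moments
#'
#' Per-coordinate streaming first and second moments with a forgetting
#' factor. A `running_moments` object tracks the effective observation count
#' `n_eff`, the weighted coordinatewise sum `S` and sum of squares `SS`
#' over the observation mode; from these the effective mean and standard
#' deviation are derived at any time. With `lambda = 1` the moments equal
#' pooled sample moments of all data seen; with `lambda < 1` each past
#' batch is discounted by `lambda` per subsequent batch.
#'
#' @param shape Integer vector: per-coordinate shape (`I1 x ... x In`).
#' @param lambda Forgetting factor in `[0, 1]`.
#' @return A `running_moments` object with fields `n_eff`, `sum`, `sum_sq`,
#'   `lambda`, `shape`.
#' @examples
#' m <- running_moments(c(2, 3), lambda = 1)
#' m <- update_moments(m, array(rnorm(5 * 2 * 3), c(5, 2, 3)))
#' ms <- mean_std(m)
#' @export
running_moments <- function(shape, lambda = 1) {
  check_lambda(lambda)
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("all mode sizes must be >= 1")
  structure(
    list(
      n_eff = 0,
      sum = array(0, shape),
      sum_sq = array(0, shape),
      lambda = lambda,
      shape = shape
    ),
    class = "running_moments"
  )
}

#' Fold one batch into a running-moments state
#'
#' Applies the exponentially weighted update
#' `n_eff <- lambda * n_eff + N`, `S <- lambda * S + colSums(batch)`,
#' `SS <- lambda * SS + colSums(batch^2)`. The input state is not modified.
#' An empty batch (`N = 0`) only decays the accumulators.
#'
#' @param state A `running_moments` object.
#' @param batch Numeric array `N x shape` (first mode = observations).
#' @return The updated `running_moments` object.
#' @export
update_moments <- function(state, batch) {
  stopifnot(inherits(state, "running_moments"))
  batch <- as_tensor(batch)
  d <- dim(batch)
  if (!identical(as.integer(d[-1L]), state$shape)) {
    stop("batch coordinate shape (", paste(d[-1L], collapse = "x"),
         ") does not match state shape (",
         paste(state$shape, collapse = "x"), ")")
  }
  lam <- state$lambda
  n <- d[1L]
  if (n == 0L) {
    state$n_eff <- lam * state$n_eff
    return(state)
  }
  if (!all(is.finite(batch))) stop("batch contains non-finite values")
  bm <- matricize_obs(batch)
  state$n_eff <- lam * state$n_eff + n
  state$sum <- array(lam * as.vector(state$sum) + .colSums(bm, n, ncol(bm)),
                     state$shape)
  state$sum_sq <- array(lam * as.vector(state$sum_sq) + .colSums(bm^2, n, ncol(bm)),
                        state$shape)
  state
}

#' Effective mean and standard deviation
#'
#' Derives the coordinatewise exponentially weighted mean `S / n_eff` and
#' standard deviation `sqrt((SS - S^2/n_eff) / (n_eff - 1))`. Requires
#' `n_eff > 1` (otherwise the variance is undefined).
#'
#' @param state A `running_moments` object.
#' @return List with arrays `mean` and `std` of the coordinate shape.
#' @export
mean_std <- function(state) {
  stopifnot(inherits(state, "running_moments"))
  if (state$n_eff <= 1) {
    stop("variance undefined: effective observation count is ", state$n_eff)
  }
  mu <- state$sum / state$n_eff
  v <- (state$sum_sq - state$sum^2 / state$n_eff) / (state$n_eff - 1)
  v[v < 0] <- 0 # guard against negative rounding residue
  list(mean = mu, std = sqrt(v))
}

#' Standardize a batch against given moments
#'
#' Coordinatewise `(batch - mean) / max(std, eps)` over the observation
#' mode. The `eps` guard keeps constant (zero-variance) coordinates finite.
#'
#' @param batch Numeric array `N x shape`.
#' @param mean,std Arrays of the coordinate shape (as from [mean_std()]).
#' @param eps Zero-variance guard.
#' @return Standardized array of the same shape as `batch`.
#' @export
standardize <- function(batch, mean, std, eps = 1e-12) {
  batch <- as_tensor(batch)
  d <- dim(batch)
  n <- d[1L]
  bm <- matricize_obs(batch)
  out <- (bm - rep(as.vector(mean), each = n)) /
    rep(pmax(as.vector(std), eps), each = n)
  tensorize_obs(out, d[-1L])
}

#' @rdname standardize
#' @description `destandardize()` inverts the transform:
#'   `batch * max(std, eps) + mean`.
#' @export
destandardize <- function(batch, mean, std, eps = 1e-12) {
  batch <- as_tensor(batch)
  d <- dim(batch)
  n <- d[1L]
  bm <- matricize_obs(batch)
  out <- bm * rep(pmax(as.vector(std), eps), each = n) +
    rep(as.vector(mean), each = n)
  tensorize_obs(out, d[-1L])
}

check_lambda <- function(lambda, name = "lambda") {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop(name, " must be a single number in [0, 1]")
  }
  invisible(lambda)
}
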