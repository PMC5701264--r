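#' Specify a synthetic tensor-regression stream
#'
#' Ground-truth generator for validating the streaming estimator: a known
#' coefficient tensor of given multilinear rank, standard normal inputs,
#' Gaussian observation noise at a prescribed signal-to-noise ratio, and an
#' optional mid-stream drift of the true model. The default geometry mirrors
#' an adaptive-decoder protocol: 100-epoch batches and 70 batches per run.
#'
#' @param x_shape,y_shape Mode sizes of the input / output tensors.
#' @param rank True number of rank-one components of the coefficient tensor.
#' @param snr Signal-to-noise ratio (variance ratio, per output coordinate);
#'   `Inf` for noiseless streams.
#' @param batch_size Epochs per batch.
#' @param n_batches Number of batches.
#' @param drift `"none"`; `"switch"` (the true tensor is replaced at batch
#'   `switch_at`); or `"rotation"` (continuous blend between two true
#'   tensors at `rotation_rate` radians per batch).
#' @param switch_at Batch index at which the switch happens (first batch
#'   drawn from the new truth).
#' @param rank2 Rank of the post-switch (or blend target) tensor; defaults
#'   to `rank`.
#' @param rotation_rate Radians per batch for `drift = "rotation"`.
#' @param seed Integer seed; everything the generator draws is a
#'   deterministic function of it.
#' @return A `stream_spec` object.
#' @seealso [make_truth()], [gen_batches()]
#' @export
stream_spec <- function(x_shape, y_shape, rank, snr = Inf,
                        batch_size = 100L, n_batches = 70L,
                        drift = c("none", "switch", "rotation"),
                        switch_at = NULL, rank2 = NULL,
                        rotation_rate = 0.05, seed = 1L) {
  drift <- match.arg(drift)
  x_shape <- as.integer(x_shape)
  y_shape <- as.integer(y_shape)
  if (rank < 1L) stop("rank must be >= 1")
  if (!(snr > 0)) stop("snr must be positive")
  if (drift == "switch" && is.null(switch_at)) {
    switch_at <- n_batches %/% 2L + 1L
  }
  structure(
    list(x_shape = x_shape, y_shape = y_shape, rank = as.integer(rank),
         snr = snr, batch_size = as.integer(batch_size),
         n_batches = as.integer(n_batches), drift = drift,
         switch_at = switch_at, rank2 = if (is.null(rank2)) rank else as.integer(rank2),
         rotation_rate = rotation_rate, seed = as.integer(seed)),
    class = "stream_spec"
  )
}

#' Draw the ground-truth model of a stream
#'
#' The true coefficient tensor is `B = sum_r alpha_r w_r^1 o ... o w_r^n o
#' q_r^1 o ... o q_r^m` with unit-norm factors drawn reproducibly from the
#' spec's seed and unit component scales. Input-side factors are scaled so
#' signal variance per output coordinate is O(1) regardless of `prod(x_shape)`.
#' For drifting streams a second, independent truth (`B2`) is drawn as well.
#'
#' @param spec A [stream_spec()].
#' @return A `stream_truth` object: `B` (matricized `I x J` true tensor),
#'   `B_tensor`, factors (`x_factors`, `y_factors`, `alphas`), and for
#'   drifting streams `B2` and its factors.
#' @export
make_truth <- function(spec) {
  stopifnot(inherits(spec, "stream_spec"))
  if (max(spec$rank, spec$rank2) > prod(spec$x_shape)) {
    stop("rank exceeds the input mode product")
  }
  withr::with_seed(spec$seed, {
    t1 <- draw_truth_component(spec$x_shape, spec$y_shape, spec$rank)
    out <- list(B = t1$B, B_tensor = array(t1$B, c(spec$x_shape, spec$y_shape)),
                x_factors = t1$x_factors, y_factors = t1$y_factors,
                alphas = t1$alphas)
    if (spec$drift != "none") {
      t2 <- draw_truth_component(spec$x_shape, spec$y_shape, spec$rank2)
      out$B2 <- t2$B
      out$B2_tensor <- array(t2$B, c(spec$x_shape, spec$y_shape))
      out$x_factors2 <- t2$x_factors
      out$y_factors2 <- t2$y_factors
      out$alphas2 <- t2$alphas
    }
    class(out) <- "stream_truth"
    out
  })
}

draw_truth_component <- function(x_shape, y_shape, rank) {
  I <- prod(x_shape)
  J <- prod(y_shape)
  x_factors <- vector("list", rank)
  y_factors <- vector("list", rank)
  alphas <- rep(1, rank)
  B <- matrix(0, I, J)
  for (r in seq_len(rank)) {
    xv <- lapply(x_shape, rnorm_unit)
    yv <- lapply(y_shape, rnorm_unit)
    x_factors[[r]] <- xv
    y_factors[[r]] <- yv
    B <- B + alphas[r] * tcrossprod(vec_outer(xv), vec_outer(yv))
  }
  list(B = B, x_factors = x_factors, y_factors = y_factors, alphas = alphas)
}

rnorm_unit <- function(n) {
  v <- stats::rnorm(n)
  v / sqrt(sum(v^2))
}

#' Generate the batches of a stream
#'
#' Inputs are i.i.d. standard normal; responses are `Y = X B + noise` with
#' per-output-coordinate noise variance `Var(signal) / snr` (signal variance
#' is the exact column sum of squares of the true tensor, since the inputs
#' are standard normal). Under `drift = "switch"` the post-switch batches
#' use the second truth; under `"rotation"` batch `t` uses
#' `cos(theta_t) B + sin(theta_t) B2`, `theta_t = min(rate * (t-1), pi/2)`.
#'
#' @param spec A [stream_spec()].
#' @param truth The matching [make_truth()] result.
#' @param n_batches Number of batches to draw (defaults to the spec's).
#' @return List of batches; each batch is a list with arrays `x`
#'   (`batch_size x x_shape`) and `y` (`batch_size x y_shape`), plus the
#'   batch index `t`.
#' @export
gen_batches <- function(spec, truth, n_batches = NULL) {
  stopifnot(inherits(spec, "stream_spec"), inherits(truth, "stream_truth"))
  if (is.null(n_batches)) n_batches <- spec$n_batches
  withr::with_seed(spec$seed + 1L,
    lapply(seq_len(n_batches), function(t) draw_batch(spec, truth, t))
  )
}

draw_batch <- function(spec, truth, t) {
  B <- batch_truth(spec, truth, t)
  I <- prod(spec$x_shape)
  J <- prod(spec$y_shape)
  L <- spec$batch_size
  X <- matrix(stats::rnorm(L * I), L, I)
  Y <- X %*% B
  if (is.finite(spec$snr)) {
    sd_noise <- sqrt(colSums(B^2) / spec$snr)
    Y <- Y + matrix(stats::rnorm(L * J), L, J) *
      rep(sd_noise, each = L)
  }
  list(x = tensorize_obs(X, spec$x_shape),
       y = tensorize_obs(Y, spec$y_shape),
       t = t)
}

# the effective true matricized tensor for batch t
batch_truth <- function(spec, truth, t) {
  switch(spec$drift,
    none = truth$B,
    switch = if (t >= spec$switch_at) truth$B2 else truth$B,
    rotation = {
      theta <- min(spec$rotation_rate * (t - 1L), pi / 2)
      cos(theta) * truth$B + sin(theta) * truth$B2
    }
  )
}
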