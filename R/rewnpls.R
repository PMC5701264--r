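#' Initialize a streaming REW-NPLS estimator
#'
#' Creates the empty state of the recursive exponentially weighted N-way PLS
#' estimator for paired observation tensors `X` (`N x I1 x ... x In`) and
#' `Y` (`N x J1 x ... x Jm`). The state holds exponentially weighted raw
#' cross-product accumulators (`sum x x'` and `sum x y'` over vectorized
#' epochs) together with running first/second moments of both blocks; the
#' centered, scaled covariance tensors needed for factor extraction are
#' derived from these analytically, so recentring is exact at every update.
#'
#' @param x_shape Integer vector of input mode sizes (`I1, ..., In`).
#' @param y_shape Integer vector of output mode sizes (`J1, ..., Jm`).
#' @param lambda Forgetting factor in `[0, 1]`; `1` keeps all past batches
#'   with equal weight, smaller values discount old batches exponentially.
#' @param f_max Maximum number of latent factors; all intermediate models
#'   `B^1 ... B^f_max` are maintained at every update.
#' @param scale_y Standardize the output block by its running standard
#'   deviation (as well as centering it)? Default `TRUE`.
#' @param eps Zero-variance guard used wherever a standard deviation divides.
#' @return An object of class `rewnpls_state`.
#' @seealso [rewnpls_update()], [predict.rewnpls_state()], [rv_init()]
#' @examples
#' st <- rewnpls_init(c(4, 3), 2, lambda = 1, f_max = 3)
#' @export
rewnpls_init <- function(x_shape, y_shape, lambda = 1, f_max,
                         scale_y = TRUE, eps = 1e-12) {
  check_lambda(lambda)
  x_shape <- as.integer(x_shape)
  y_shape <- as.integer(y_shape)
  if (any(x_shape < 1L) || any(y_shape < 1L)) stop("all mode sizes must be >= 1")
  if (!is.numeric(f_max) || length(f_max) != 1L || f_max < 1) {
    stop("f_max must be >= 1")
  }
  f_max <- as.integer(f_max)
  I <- prod(x_shape)
  J <- prod(y_shape)
  structure(
    list(
      x_shape = x_shape, y_shape = y_shape, I = I, J = J,
      lambda = lambda, f_max = f_max, scale_y = scale_y, eps = eps,
      x_mom = running_moments(x_shape, lambda),
      y_mom = running_moments(y_shape, lambda),
      sxx = matrix(0, I, I),
      sxy = matrix(0, I, J),
      stack = empty_stack(x_shape, y_shape, f_max),
      updates = 0L
    ),
    class = "rewnpls_state"
  )
}

empty_stack <- function(x_shape, y_shape, f_max) {
  I <- prod(x_shape)
  J <- prod(y_shape)
  structure(
    list(
      f_max = as.integer(f_max), valid = 0L,
      x_shape = x_shape, y_shape = y_shape,
      B = rep(list(matrix(0, I, J)), f_max),
      R = matrix(0, I, 0), P = matrix(0, I, 0), Q = matrix(0, J, 0),
      W = matrix(0, I, 0),
      projectors = vector("list", f_max),
      mean_x = numeric(I), std_x = rep(1, I),
      mean_y = numeric(J), std_y = rep(1, J),
      scale_y = TRUE, eps = 1e-12,
      updates = 0L
    ),
    class = "model_stack"
  )
}

#' Update the estimator with one batch
#'
#' Performs one streaming step: (i) fold the batch into the running moments
#' of both blocks, (ii) add the batch's raw cross-products to the
#' exponentially weighted accumulators (`lambda`-decayed), (iii) derive the
#' centered, scaled covariance matrices and (iv) re-extract the full stack
#' of intermediate models `B^1 ... B^f_max` with the covariance-kernel
#' recursion, warm-starting each factor's rank-one PARAFAC at its previous
#' projectors. An empty batch only decays the accumulators.
#'
#' @param state A `rewnpls_state`.
#' @param x_batch Numeric array `L x I1 x ... x In`.
#' @param y_batch Numeric array `L x J1 x ... x Jm`.
#' @param als_tol,als_max_iter Stopping controls for the per-factor rank-one
#'   PARAFAC (tight by default so that re-extractions are reproducible).
#' @param use_warm_start Also try the previous update's projectors as ALS
#'   starting points (keeping whichever candidate attains the higher
#'   objective). Default `FALSE`: the extracted model is then a deterministic
#'   function of the covariance statistics alone, so any batch partition of
#'   the same epochs gives the same model. Enable for latency-critical
#'   streaming, accepting that a warm candidate can occasionally settle a
#'   factor on a different (better) stationary point than the cold start.
#' @return The updated `rewnpls_state` (input unmodified).
#' @export
rewnpls_update <- function(state, x_batch, y_batch,
                           als_tol = 1e-10, als_max_iter = 200L,
                           use_warm_start = FALSE) {
  stopifnot(inherits(state, "rewnpls_state"))
  x_batch <- as_tensor(x_batch)
  y_batch <- as_tensor(y_batch)
  dx <- dim(x_batch)
  dy <- dim(y_batch)
  if (!identical(as.integer(dx[-1L]), state$x_shape) ||
      !identical(as.integer(dy[-1L]), state$y_shape)) {
    stop("batch shapes do not match the state's x_shape/y_shape")
  }
  if (dx[1L] != dy[1L]) stop("X and Y batches disagree in epoch count")
  L <- dx[1L]
  lam <- state$lambda
  if (L == 0L) {
    state$x_mom <- update_moments(state$x_mom, x_batch)
    state$y_mom <- update_moments(state$y_mom, y_batch)
    state$sxx <- lam * state$sxx
    state$sxy <- lam * state$sxy
    return(state)
  }
  if (!all(is.finite(x_batch)) || !all(is.finite(y_batch))) {
    stop("batch contains non-finite values")
  }

  state$x_mom <- update_moments(state$x_mom, x_batch)
  state$y_mom <- update_moments(state$y_mom, y_batch)
  xm <- matricize_obs(x_batch)
  ym <- matricize_obs(y_batch)
  state$sxx <- lam * state$sxx + crossprod(xm)
  state$sxy <- lam * state$sxy + crossprod(xm, ym)
  state$updates <- state$updates + 1L

  if (state$x_mom$n_eff > 1) {
    cov <- derived_covariances(state)
    warm <- if (use_warm_start && state$stack$valid > 0L) state$stack$projectors else NULL
    stack <- extract_factors(cov$cxx, cov$cxy, state$x_shape, state$y_shape,
                             state$f_max, warm_start = warm,
                             als_tol = als_tol, als_max_iter = als_max_iter)
    stack$mean_x <- cov$mean_x; stack$std_x <- cov$std_x
    stack$mean_y <- cov$mean_y; stack$std_y <- cov$std_y
    stack$scale_y <- state$scale_y
    stack$eps <- state$eps
    stack$updates <- state$updates
    state$stack <- stack
  } else {
    state$stack$updates <- state$updates
  }
  state
}

# centered, scaled covariance matrices from the raw accumulators:
# Cxx = (sxx - S S'/n_eff) / (sx sx'),  Cxy likewise with the y block
derived_covariances <- function(state) {
  msx <- mean_std(state$x_mom)
  msy <- mean_std(state$y_mom)
  n_eff <- state$x_mom$n_eff
  sx_vec <- as.vector(state$x_mom$sum)
  sy_vec <- as.vector(state$y_mom$sum)
  sdx <- pmax(as.vector(msx$std), state$eps)
  sdy <- if (state$scale_y) pmax(as.vector(msy$std), state$eps) else rep(1, state$J)
  cxx <- (state$sxx - tcrossprod(sx_vec) / n_eff) / tcrossprod(sdx)
  cxy <- (state$sxy - tcrossprod(sx_vec, sy_vec) / n_eff) / tcrossprod(sdx, sdy)
  list(cxx = cxx, cxy = cxy,
       mean_x = as.vector(msx$mean), std_x = sdx,
       mean_y = as.vector(msy$mean), std_y = sdy)
}

#' Extract all intermediate models from covariance matrices
#'
#' Covariance-only kernel recursion producing the whole stack of
#' intermediate models `B^1 ... B^f_max`. Per factor `f`:
#' \enumerate{
#'   \item reshape the current (deflated) `Cxy` to an `(n+m)`-mode tensor and
#'     take its best rank-one PARAFAC approximation (warm-started when
#'     previous projectors are available); the input-side projectors
#'     `w_f^1 ... w_f^n` define `w_f = vec(w_f^1 o ... o w_f^n)`;
#'   \item orthogonalize: `r_f = w_f - sum_(j<f) (p_j' w_f) r_j`;
#'   \item `tt_f = r_f' Cxx r_f` (factor abandoned if below the degeneracy
#'     guard `eps_tt * trace(Cxx)`);
#'   \item loadings `p_f = Cxx r_f / tt_f`, `q_f = Cxy' r_f / tt_f`;
#'   \item deflate `Cxy <- Cxy - tt_f p_f q_f'`;
#'   \item `B^f = B^(f-1) + r_f q_f'` (matricized).
#' }
#' If a factor is degenerate the stack truncates there and later models alias
#' the last valid one.
#'
#' @param cxx Symmetric PSD matrix `I x I` (centered, scaled input covariance).
#' @param cxy Matrix `I x J` (centered, scaled cross-covariance).
#' @param x_shape,y_shape Mode sizes with `prod(x_shape) == I`,
#'   `prod(y_shape) == J`.
#' @param f_max Number of factors to extract.
#' @param warm_start Optional list (per factor) of previous projector vector
#'   lists, as stored in a returned stack's `projectors` field.
#' @param als_tol,als_max_iter Rank-one PARAFAC stopping controls.
#' @param eps_tt Relative degeneracy guard on `tt_f`.
#' @return A `model_stack` object (moment snapshot fields unset).
#' @export
extract_factors <- function(cxx, cxy, x_shape, y_shape, f_max,
                            warm_start = NULL,
                            als_tol = 1e-10, als_max_iter = 200L,
                            eps_tt = 1e-12) {
  x_shape <- as.integer(x_shape)
  y_shape <- as.integer(y_shape)
  I <- prod(x_shape)
  J <- prod(y_shape)
  stopifnot(nrow(cxx) == I, ncol(cxx) == I, nrow(cxy) == I, ncol(cxy) == J)
  stack <- empty_stack(x_shape, y_shape, f_max)
  n_x <- length(x_shape)
  tt_guard <- eps_tt * max(sum(diag(cxx)), .Machine$double.xmin)

  B <- matrix(0, I, J)
  R <- matrix(0, I, f_max)
  P <- matrix(0, I, f_max)
  Q <- matrix(0, J, f_max)
  W <- matrix(0, I, f_max)
  valid <- 0L
  cxy_defl <- cxy

  for (f in seq_len(f_max)) {
    cxy_tensor <- array(cxy_defl, c(x_shape, y_shape))
    # always run the deterministic cold start; a warm start (previous
    # projectors) is a second candidate and wins only on a strictly higher
    # objective, so extraction stays a function of the covariances alone
    # whenever the cold start reaches the dominant stationary point
    pf <- rank_one_parafac(cxy_tensor, n_x, init = NULL,
                           tol = als_tol, max_iter = als_max_iter)
    init <- if (!is.null(warm_start) && length(warm_start) >= f) warm_start[[f]] else NULL
    if (!is.null(init)) {
      pw <- rank_one_parafac(cxy_tensor, n_x, init = init,
                             tol = als_tol, max_iter = als_max_iter)
      if (!pw$degenerate && pw$scale > pf$scale * (1 + 1e-9)) pf <- pw
    }
    if (pf$degenerate) break
    w <- vec_outer(pf$x_vectors)
    r <- w
    if (valid > 0L) {
      proj <- crossprod(P[, seq_len(valid), drop = FALSE], w)
      r <- w - R[, seq_len(valid), drop = FALSE] %*% proj
    }
    tt <- drop(crossprod(r, cxx %*% r))
    if (!is.finite(tt) || tt <= tt_guard) break
    p <- cxx %*% r / tt
    q <- crossprod(cxy_defl, r) / tt
    cxy_defl <- cxy_defl - tt * tcrossprod(p, q)
    B <- B + tcrossprod(r, q)
    valid <- f
    R[, f] <- r; P[, f] <- p; Q[, f] <- q; W[, f] <- w
    stack$projectors[[f]] <- c(pf$x_vectors, pf$y_vectors)
    stack$B[[f]] <- B
  }

  if (valid < f_max && valid >= 0L) {
    last <- if (valid == 0L) matrix(0, I, J) else stack$B[[valid]]
    for (f in seq((valid + 1L), f_max)) stack$B[[f]] <- last
  }
  stack$valid <- valid
  stack$R <- R[, seq_len(valid), drop = FALSE]
  stack$P <- P[, seq_len(valid), drop = FALSE]
  stack$Q <- Q[, seq_len(valid), drop = FALSE]
  stack$W <- W[, seq_len(valid), drop = FALSE]
  stack
}

# vec of the outer product of a list of vectors (first vector fastest)
vec_outer <- function(vs) {
  out <- 1
  for (v in vs) out <- outer(out, v)
  as.vector(out)
}

#' Predict responses from a fitted model stack
#'
#' Applies the `f`-factor intermediate model to raw (non-centered,
#' non-scaled) input tensors using the de-normalized coefficients
#' `B~ = B * sd_Y / sd_X` and intercept `Y0 = mu_Y - mu_X . B~`, which is
#' algebraically identical to standardizing the input, applying the centered
#' model, and de-standardizing the prediction.
#'
#' @param object A `model_stack` or `rewnpls_state`.
#' @param newdata Numeric array `N x I1 x ... x In` of raw inputs.
#' @param f Number of factors to use; defaults to all valid factors. If `f`
#'   exceeds the valid count the last valid model is used with a warning.
#' @param ... Unused.
#' @return Numeric array `N x J1 x ... x Jm` of predicted responses.
#' @export
predict.model_stack <- function(object, newdata, f = NULL, ...) {
  stack <- object
  newdata <- as_tensor(newdata)
  d <- dim(newdata)
  if (!identical(as.integer(d[-1L]), stack$x_shape)) {
    stop("newdata shape does not match the model's x_shape")
  }
  if (!all(is.finite(newdata))) stop("newdata contains non-finite values")
  if (is.null(f)) f <- max(stack$valid, 1L)
  if (f < 1L) stop("f must be >= 1")
  if (f > stack$valid) {
    if (stack$valid == 0L) {
      # intercept-only model: prediction is the running mean of Y
      n <- d[1L]
      out <- matrix(rep(stack$mean_y, each = n), n)
      return(tensorize_obs(out, stack$y_shape))
    }
    warning("f = ", f, " exceeds the ", stack$valid,
            "-factor stack; using the last valid model")
    f <- stack$valid
  }
  bt <- denormalized_coef(stack, f)
  xm <- matricize_obs(newdata)
  out <- xm %*% bt$B_tilde + rep(bt$y0, each = d[1L])
  tensorize_obs(out, stack$y_shape)
}

#' @rdname predict.model_stack
#' @export
predict.rewnpls_state <- function(object, newdata, f = NULL, ...) {
  predict.model_stack(object$stack, newdata, f = f, ...)
}

# de-normalization: B~[i, j] = B[i, j] * sd_y[j] / sd_x[i];
# y0 = mu_y - mu_x %*% B~
denormalized_coef <- function(stack, f) {
  B <- stack$B[[f]]
  B_tilde <- B * (rep(stack$std_y, each = nrow(B)) / stack$std_x)
  y0 <- stack$mean_y - drop(stack$mean_x %*% B_tilde)
  list(B_tilde = B_tilde, y0 = y0)
}

#' Extract coefficient tensors
#'
#' @param object A `model_stack` or `rewnpls_state`.
#' @param f Number of factors (defaults to all valid factors).
#' @param denormalized If `TRUE`, return the de-normalized coefficients that
#'   apply to raw data (with the intercept as attribute `intercept`);
#'   otherwise the standardized-scale coefficients.
#' @param ... Unused.
#' @return Numeric array of shape `I1 x ... x In x J1 x ... x Jm`.
#' @export
coef.model_stack <- function(object, f = NULL, denormalized = FALSE, ...) {
  if (is.null(f)) f <- max(object$valid, 1L)
  f <- min(f, max(object$valid, 1L))
  if (denormalized) {
    bt <- denormalized_coef(object, f)
    out <- array(bt$B_tilde, c(object$x_shape, object$y_shape))
    attr(out, "intercept") <- array(bt$y0, object$y_shape)
    out
  } else {
    array(object$B[[f]], c(object$x_shape, object$y_shape))
  }
}

#' @rdname coef.model_stack
#' @export
coef.rewnpls_state <- function(object, f = NULL, denormalized = FALSE, ...) {
  coef.model_stack(object$stack, f = f, denormalized = denormalized, ...)
}

#' @export
print.rewnpls_state <- function(x, ...) {
  cat("<rewnpls_state>\n",
      " x_shape: ", paste(x$x_shape, collapse = " x "),
      "  y_shape: ", paste(x$y_shape, collapse = " x "), "\n",
      " lambda: ", x$lambda, "  f_max: ", x$f_max,
      "  updates: ", x$updates,
      "  valid factors: ", x$stack$valid, "\n", sep = "")
  invisible(x)
}

#' @export
print.model_stack <- function(x, ...) {
  cat("<model_stack> ", x$valid, "/", x$f_max, " factors, x_shape ",
      paste(x$x_shape, collapse = "x"), ", y_shape ",
      paste(x$y_shape, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Save / load a fitted streaming state
#'
#' Serializes the full estimator state (accumulators, moments, projectors,
#' all intermediate models, provenance fields) so a stream can be resumed or
#' a model applied elsewhere.
#'
#' @param state A `rewnpls_state`.
#' @param path File path.
#' @return `load_model()` returns the restored `rewnpls_state`.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "rewnpls_state"))
  obj <- list(state = state,
              package_version = as.character(utils::packageVersion("rewnpls")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj$state, "rewnpls_state"))
  obj$state
}
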