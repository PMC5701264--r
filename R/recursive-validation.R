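#' Online number-of-factors selection by recursive validation
#'
#' Recursive validation treats every incoming batch as a test set for all
#' intermediate models *before* they are updated with that batch. Per-factor
#' prediction errors are accumulated with a forgetting factor `gamma`
#' (`e^f <- gamma * e^f + ERROR(Yhat^f, Y)`), and the current optimal factor
#' count is `F* = argmin_f e^f` with the smallest index winning ties
#' (parsimony).
#'
#' @param f_max Maximum factor count tracked (must match the estimator's).
#' @param gamma Forgetting factor in `[0, 1]` for the error accumulators;
#'   `1` accumulates all batches equally, `0` keeps only the current batch.
#' @param error Error functional: `"mse"` (mean squared error over epochs and
#'   output coordinates) or `"nmse"` (squared error per output coordinate
#'   divided by that coordinate's running variance, then averaged — invariant
#'   to the scale of `Y`).
#' @return An object of class `rv_state` with fields `errors`, `gamma`,
#'   `f_star`, `batches_seen`.
#' @seealso [rv_update()], [select_model()], [decode_stream()]
#' @export
rv_init <- function(f_max, gamma = 1, error = c("mse", "nmse")) {
  check_lambda(gamma, "gamma")
  error <- match.arg(error)
  if (!is.numeric(f_max) || length(f_max) != 1L || f_max < 1) {
    stop("f_max must be >= 1")
  }
  structure(
    list(
      errors = numeric(as.integer(f_max)),
      gamma = gamma,
      f_star = 1L,
      batches_seen = 0L,
      f_max = as.integer(f_max),
      error = error
    ),
    class = "rv_state"
  )
}

#' Score all intermediate models on a new batch
#'
#' Must be called with the model stack from *before* this batch's covariance
#' update (the pre-update/test, post-update/train ordering is the point of
#' the procedure); this is enforced by an update-counter handshake with the
#' estimator. On the very first batch (no model yet) the call only advances
#' the counter.
#'
#' @param rv An `rv_state`.
#' @param state The `rewnpls_state` (or its `model_stack`) prior to updating
#'   with this batch.
#' @param x_batch,y_batch The new batch (`L >= 1` epochs).
#' @return The updated `rv_state`.
#' @export
rv_update <- function(rv, state, x_batch, y_batch) {
  stopifnot(inherits(rv, "rv_state"))
  stack <- if (inherits(state, "rewnpls_state")) state$stack else state
  stopifnot(inherits(stack, "model_stack"))
  if (stack$f_max != rv$f_max) stop("rv and model stack disagree on f_max")
  if (stack$updates != rv$batches_seen) {
    stop("ordering violation: rv_update() must see the pre-update model ",
         "(model has ", stack$updates, " updates, rv has scored ",
         rv$batches_seen, " batches)")
  }
  x_batch <- as_tensor(x_batch)
  y_batch <- as_tensor(y_batch)
  if (dim(x_batch)[1L] < 1L) stop("batch must be nonempty")

  if (stack$valid > 0L) {
    ym <- matricize_obs(y_batch)
    errs <- vapply(seq_len(rv$f_max), function(f) {
      pred <- matricize_obs(predict.model_stack(stack, x_batch, f = min(f, stack$valid)))
      se <- (pred - ym)^2
      if (rv$error == "nmse") {
        se <- se / rep(pmax(stack$std_y^2, stack$eps), each = nrow(se))
      }
      mean(se)
    }, numeric(1))
    rv$errors <- rv$gamma * rv$errors + errs
    rv$f_star <- which.min(rv$errors) # which.min takes the smallest index on ties
  }
  rv$batches_seen <- rv$batches_seen + 1L
  rv
}

#' Select the currently optimal model
#'
#' Returns a light handle on the `F*`-factor intermediate model. Before any
#' batch has been scored the 1-factor model is returned with a cold-start
#' flag.
#'
#' @param rv An `rv_state`.
#' @param state The `rewnpls_state` (or `model_stack`) holding the stack.
#' @return List with `f` (selected factor count), `B` (coefficient tensor,
#'   standardized scale), `B_tilde` and `y0` (de-normalized coefficients and
#'   intercept for raw data), `cold_start`.
#' @export
select_model <- function(rv, state) {
  stopifnot(inherits(rv, "rv_state"))
  stack <- if (inherits(state, "rewnpls_state")) state$stack else state
  stopifnot(inherits(stack, "model_stack"))
  if (stack$valid == 0L) stop("no model: the stack has no valid factors yet")
  cold <- rv$batches_seen == 0L || all(rv$errors == 0)
  f <- if (cold) 1L else min(rv$f_star, stack$valid)
  bt <- denormalized_coef(stack, f)
  list(
    f = f,
    B = array(stack$B[[f]], c(stack$x_shape, stack$y_shape)),
    B_tilde = array(bt$B_tilde, c(stack$x_shape, stack$y_shape)),
    y0 = array(bt$y0, stack$y_shape),
    cold_start = cold
  )
}

#' @export
print.rv_state <- function(x, ...) {
  cat("<rv_state> gamma ", x$gamma, ", ", x$batches_seen,
      " batches scored, F* = ", x$f_star, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-factor validation errors
#'
#' @param x An `rv_state`.
#' @param ... Unused.
#' @return A tibble with columns `factors`, `error`, `selected`.
#' @export
tidy.rv_state <- function(x, ...) {
  tibble::tibble(
    factors = seq_len(x$f_max),
    error = x$errors,
    selected = seq_len(x$f_max) == x$f_star
  )
}

#' One-row summaries of fitted objects
#'
#' @param x An `rv_state` or `rewnpls_state`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.rv_state <- function(x, ...) {
  tibble::tibble(
    f_star = x$f_star,
    batches_seen = x$batches_seen,
    gamma = x$gamma,
    min_error = if (x$batches_seen > 0L) min(x$errors) else NA_real_
  )
}

#' @rdname glance.rv_state
#' @export
glance.rewnpls_state <- function(x, ...) {
  tibble::tibble(
    updates = x$updates,
    n_eff = x$x_mom$n_eff,
    lambda = x$lambda,
    f_max = x$f_max,
    valid_factors = x$stack$valid
  )
}
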