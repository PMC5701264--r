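#' Run the adaptive streaming protocol over a batch sequence
#'
#' Binds the estimator and the recursive-validation selector into the
#' apply-then-update loop: for every batch the pre-update model stack is
#' first scored on the batch ([rv_update()]), then the batch is folded into
#' the estimator ([rewnpls_update()]). Optionally each post-update model is
#' evaluated on a fixed held-out test set.
#'
#' @param state A fresh or resumed [rewnpls_init()] state.
#' @param rv A matching [rv_init()] state.
#' @param batches List of batches, each a list with arrays `x` and `y`
#'   (as produced by [gen_batches()]).
#' @param test_x,test_y Optional held-out tensors; when given, the selected
#'   model's per-coordinate Pearson correlation with `test_y` (averaged over
#'   output coordinates) is recorded after each update.
#' @param als_tol,als_max_iter,use_warm_start Passed to [rewnpls_update()].
#' @return List with the final `state`, `rv`, and `trace`: a tibble with one
#'   row per batch (`batch`, `f_star`, `e_1 ... e_Fmax` as a list column
#'   `errors`, `test_r`).
#' @export
decode_stream <- function(state, rv, batches, test_x = NULL, test_y = NULL,
                          als_tol = 1e-10, als_max_iter = 200L,
                          use_warm_start = FALSE) {
  stopifnot(inherits(state, "rewnpls_state"), inherits(rv, "rv_state"))
  n <- length(batches)
  f_star <- integer(n)
  test_r <- rep(NA_real_, n)
  errors <- vector("list", n)
  for (t in seq_len(n)) {
    b <- batches[[t]]
    rv <- rv_update(rv, state, b$x, b$y)
    state <- rewnpls_update(state, b$x, b$y,
                            als_tol = als_tol, als_max_iter = als_max_iter,
                            use_warm_start = use_warm_start)
    f_star[t] <- rv$f_star
    errors[[t]] <- rv$errors
    if (!is.null(test_x)) {
      sel <- select_model(rv, state)
      pred <- predict(state, test_x, f = sel$f)
      test_r[t] <- mean(pearson_scores(pred, test_y))
    }
  }
  trace <- tibble::tibble(batch = seq_len(n), f_star = f_star,
                          errors = errors, test_r = test_r)
  class(trace) <- c("rv_trace", class(trace))
  list(state = state, rv = rv, trace = trace)
}

#' One-shot offline fit
#'
#' Initializes a state and performs a single update on the full data; with
#' `lambda = 1` this is algebraically identical to streaming the same epochs
#' in any batch partition.
#'
#' @param x,y Observation tensors (`N x I1 x ... x In`, `N x J1 x ... x Jm`).
#' @param f_max Number of factors to extract.
#' @param lambda,scale_y,... Passed to [rewnpls_init()] / [rewnpls_update()].
#' @return A fitted `rewnpls_state`.
#' @export
fit_offline <- function(x, y, f_max, lambda = 1, scale_y = TRUE, ...) {
  x <- as_tensor(x)
  y <- as_tensor(y)
  state <- rewnpls_init(dim(x)[-1L], dim(y)[-1L], lambda = lambda,
                        f_max = f_max, scale_y = scale_y)
  rewnpls_update(state, x, y, ...)
}

#' Per-coordinate Pearson correlation of predictions
#'
#' The decoder-accuracy metric: Pearson correlation between predicted and
#' observed responses, computed per output coordinate (coordinates with zero
#' variance on either side yield `NA`).
#'
#' @param pred,obs Arrays `N x J1 x ... x Jm`.
#' @return Named numeric vector of length `prod(J)` of correlations.
#' @export
pearson_scores <- function(pred, obs) {
  pm <- matricize_obs(as_tensor(pred))
  om <- matricize_obs(as_tensor(obs))
  stopifnot(identical(dim(pm), dim(om)))
  vapply(seq_len(ncol(pm)), function(j) {
    if (stats::sd(pm[, j]) == 0 || stats::sd(om[, j]) == 0) return(NA_real_)
    stats::cor(pm[, j], om[, j])
  }, numeric(1))
}

#' Tidy a streaming trace
#'
#' @param x An `rv_trace` (from [decode_stream()]).
#' @param ... Unused.
#' @return Long tibble with columns `batch`, `factors`, `error`, `f_star`,
#'   `test_r`.
#' @export
tidy.rv_trace <- function(x, ...) {
  n <- nrow(x)
  fm <- length(x$errors[[1L]])
  tibble::tibble(
    batch = rep(x$batch, each = fm),
    factors = rep(seq_len(fm), n),
    error = unlist(x$errors),
    f_star = rep(x$f_star, each = fm),
    test_r = rep(x$test_r, each = fm)
  )
}

#' Plot the factor-selection trajectory of a stream
#'
#' @param object An `rv_trace`.
#' @param ... Unused.
#' @return A ggplot object: accumulated error per factor count over batches,
#'   with the selected `F*` trajectory overlaid.
#' @export
autoplot.rv_trace <- function(object, ...) {
  long <- tidy.rv_trace(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$batch, y = .data$error,
                                     group = .data$factors,
                                     colour = factor(.data$factors))) +
    ggplot2::geom_line() +
    ggplot2::geom_step(
      data = object,
      mapping = ggplot2::aes(x = .data$batch, y = .data$f_star),
      inherit.aes = FALSE
    ) +
    ggplot2::labs(colour = "factors", y = "accumulated error / F*")
}

#' Write / read a streaming trace as TSV
#'
#' One row per batch: batch index, selected factor count, held-out
#' correlation (if any), and the accumulated per-factor errors `e_1 ...`.
#'
#' @param trace An `rv_trace`.
#' @param path File path.
#' @return `read_trace()` returns the trace as a tibble (errors as columns).
#' @export
write_trace <- function(trace, path) {
  fm <- length(trace$errors[[1L]])
  flat <- do.call(rbind, trace$errors)
  colnames(flat) <- paste0("e_", seq_len(fm))
  out <- cbind(data.frame(batch = trace$batch, f_star = trace$f_star,
                          test_r = trace$test_r), flat)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
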