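# small fitted stack reused across blocks
fit_toy_stack <- function(seed = 51, n = 120, fmax = 3) {
  set.seed(seed)
  x <- array(rnorm(n * 4 * 3), c(n, 4, 3))
  y <- array(rnorm(n * 2), c(n, 2))
  fit_offline(x, y, f_max = fmax)
}

test_that("the error recursion and argmin follow the discounted-accumulation rule", {
  st <- fit_toy_stack()
  rv <- rv_init(3, gamma = 0.5)
  rv$batches_seen <- st$updates # align the handshake for a hand-set state
  rv$errors <- c(0.5, 0.4, 0.6)

  # hand-build a batch whose per-factor errors we can compute independently
  set.seed(52)
  xb <- array(rnorm(30 * 4 * 3), c(30, 4, 3))
  yb <- array(rnorm(30 * 2), c(30, 2))
  manual <- sapply(1:3, function(f) mean((predict(st, xb, f = f) - yb)^2))
  rv2 <- rv_update(rv, st, xb, yb)
  expect_equal(rv2$errors, 0.5 * c(0.5, 0.4, 0.6) + manual, tolerance = 1e-12)
  expect_equal(rv2$f_star, which.min(rv2$errors))

  # the worked recursion: e = [.5,.4,.6], gamma = .5, new = [.2,.3,.1]
  e <- 0.5 * c(0.5, 0.4, 0.6) + c(0.2, 0.3, 0.1)
  expect_equal(e, c(0.45, 0.50, 0.40))
  expect_equal(which.min(e), 3L)
})

test_that("gamma = 0 keeps only the current batch and ties break to fewer factors", {
  st <- fit_toy_stack()
  rv <- rv_init(3, gamma = 0)
  rv$batches_seen <- st$updates
  rv$errors <- c(1e6, 1e6, 1e6) # must be wiped by total forgetting
  set.seed(53)
  xb <- array(rnorm(25 * 4 * 3), c(25, 4, 3))
  yb <- array(rnorm(25 * 2), c(25, 2))
  manual <- sapply(1:3, function(f) mean((predict(st, xb, f = f) - yb)^2))
  rv2 <- rv_update(rv, st, xb, yb)
  expect_equal(rv2$errors, manual, tolerance = 1e-12)

  # exact tie: smallest index wins
  expect_equal(which.min(c(0.3, 0.3)), 1L)
  rv3 <- rv_init(2)
  rv3$errors <- c(0.3, 0.3)
  rv3$batches_seen <- 1L
  expect_equal(rv3$f_star, 1L) # untouched default, argmin would also give 1
})

test_that("the apply-before-update ordering is enforced by the counter handshake", {
  st <- fit_toy_stack()
  rv <- rv_init(3)
  set.seed(54)
  xb <- array(rnorm(20 * 4 * 3), c(20, 4, 3))
  yb <- array(rnorm(20 * 2), c(20, 2))
  # st has 1 update but rv has scored 0 batches: calling rv_update with this
  # post-update stack is an ordering violation
  expect_error(rv_update(rv, st, xb, yb), "ordering violation")

  # correct protocol: score with the pre-update model, then update
  st0 <- rewnpls_init(c(4, 3), 2, 1, 3)
  rv <- rv_update(rv, st0, xb, yb) # cold: no model yet, counter advances
  expect_equal(rv$batches_seen, 1L)
  st1 <- rewnpls_update(st0, xb, yb)
  rv <- rv_update(rv, st1, xb, yb)
  expect_equal(rv$batches_seen, 2L)
})

test_that("select_model returns the F*-factor model, with a cold-start fallback", {
  st <- fit_toy_stack()
  rv <- rv_init(3)
  rv$batches_seen <- st$updates
  rv$errors <- c(0.45, 0.50, 0.40)
  rv$f_star <- 3L
  sel <- select_model(rv, st)
  expect_equal(sel$f, 3L)
  expect_false(sel$cold_start)
  expect_equal(as.vector(sel$B), as.vector(st$stack$B[[3]]))

  rv0 <- rv_init(3)
  sel0 <- select_model(rv0, st)
  expect_equal(sel0$f, 1L)
  expect_true(sel0$cold_start)

  expect_error(select_model(rv0, rewnpls_init(c(4, 3), 2, 1, 3)), "no model")
})

test_that("normalized errors are invariant to the response scale", {
  set.seed(55)
  x <- array(rnorm(200 * 5), c(200, 5))
  y <- array(x[, 1] + 0.5 * rnorm(200), c(200, 1))
  run_with_scale <- function(s) {
    st <- rewnpls_init(5, 1, 1, 3)
    rv <- rv_init(3, gamma = 1, error = "nmse")
    for (k in 1:4) {
      idx <- ((k - 1) * 50 + 1):(k * 50)
      xb <- x[idx, , drop = FALSE]
      yb <- array(y[idx] * s, c(50, 1))
      rv <- rv_update(rv, st, xb, yb)
      st <- rewnpls_update(st, xb, yb)
    }
    rv$errors
  }
  expect_equal(run_with_scale(1), run_with_scale(100), tolerance = 1e-8)
})

test_that("with noise, recursive validation identifies a parsimonious rank", {
  # SNR-limited streams: beyond the true rank the extra factors chase
  # covariance sampling noise and the accumulated test error turns back up
  hits <- 0L
  for (seed in 1:3) {
    spec <- stream_spec(c(6, 5, 8), 3, rank = 3, snr = 1, batch_size = 100,
                        n_batches = 25, seed = 500 + seed)
    out <- run_stream(spec, lambda = 1, gamma = 1, f_max = 10)
    hits <- hits + (out$rv$f_star >= 3 && out$rv$f_star <= 5)
  }
  expect_gte(hits, 2L)
})
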