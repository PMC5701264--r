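#' Epoching and time-frequency configuration
#'
#' Describes how raw multichannel time series are mapped to
#' frequency x time x channel feature tensors: epochs of `epoch_seconds`
#' are taken every `step_seconds`; within an epoch, the modulus of the
#' complex Morlet continuous wavelet transform at `freqs` is averaged in
#' `n_time_bins` contiguous, non-overlapping temporal bins.
#'
#' @param fs Sampling rate in Hz.
#' @param epoch_seconds Epoch (analysis window) length in seconds;
#'   `epoch_seconds * fs` must be an integer number of samples.
#' @param step_seconds Epoch stride in seconds.
#' @param freqs Strictly increasing analysis frequencies (Hz), all below
#'   the Nyquist frequency `fs / 2`.
#' @param n_time_bins Number of temporal bins per epoch; must divide the
#'   epoch sample count.
#' @param morlet_width Wavelet width in cycles (the constant-Q parameter);
#'   7 is the common neurophysiology default.
#' @return An `epoch_config` object.
#' @examples
#' ecog_config() # 15 frequencies (10..150 Hz), 10 bins -> 15 x 10 x channels
#' meg_config()  # 20 frequencies (5..100 Hz)
#' @export
epoch_config <- function(fs = 1000, epoch_seconds = 1, step_seconds = 0.1,
                         freqs, n_time_bins = 10, morlet_width = 7) {
  epoch_samples <- epoch_seconds * fs
  if (abs(epoch_samples - round(epoch_samples)) > 1e-9) {
    stop("epoch_seconds * fs must be an integer sample count")
  }
  epoch_samples <- as.integer(round(epoch_samples))
  step_samples <- step_seconds * fs
  if (abs(step_samples - round(step_samples)) > 1e-9) {
    stop("step_seconds * fs must be an integer sample count")
  }
  step_samples <- as.integer(round(step_samples))
  if (epoch_samples %% n_time_bins != 0) {
    stop("n_time_bins must divide the epoch sample count (", epoch_samples, ")")
  }
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("freqs must be strictly increasing")
  }
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    stop("freqs must lie in (0, fs/2)")
  }
  if (morlet_width <= 0) stop("morlet_width must be positive")
  structure(
    list(fs = fs, epoch_seconds = epoch_seconds, step_seconds = step_seconds,
         freqs = freqs, n_time_bins = as.integer(n_time_bins),
         morlet_width = morlet_width,
         epoch_samples = epoch_samples, step_samples = step_samples),
    class = "epoch_config"
  )
}

#' @rdname epoch_config
#' @description `ecog_config()` and `meg_config()` are presets for 1 kHz
#'   recordings: 1 s epochs stepped every 100 ms, 10 temporal bins, and
#'   analysis bands of 10-150 Hz in 10 Hz steps (15 frequencies) and
#'   5-100 Hz in 5 Hz steps (20 frequencies) respectively.
#' @export
ecog_config <- function(fs = 1000, morlet_width = 7) {
  epoch_config(fs = fs, freqs = seq(10, 150, by = 10),
               morlet_width = morlet_width)
}

#' @rdname epoch_config
#' @export
meg_config <- function(fs = 1000, morlet_width = 7) {
  epoch_config(fs = fs, freqs = seq(5, 100, by = 5),
               morlet_width = morlet_width)
}

#' Morlet wavelet power of a single signal
#'
#' Modulus of the complex Morlet continuous wavelet transform at the
#' configured analysis frequencies. The transform is computed in the
#' frequency domain (a Gaussian band-pass of constant Q: center `f`,
#' standard deviation `f / morlet_width` in frequency), with zero padding
#' against circular wrap-around. The window is normalized to unit peak so a
#' unit-amplitude sinusoid at an analysis frequency yields power ~0.5 at
#' that row.
#'
#' @param signal Numeric vector of samples.
#' @param cfg An [epoch_config()].
#' @return Matrix `length(freqs) x length(signal)` of nonnegative power
#'   values, with attribute `edge_samples`: per-frequency count of samples
#'   at each end still influenced by the zero padding (3 temporal standard
#'   deviations of the wavelet).
#' @export
morlet_power <- function(signal, cfg) {
  stopifnot(inherits(cfg, "epoch_config"))
  signal <- as.numeric(signal)
  n <- length(signal)
  sigma_t <- cfg$morlet_width / (2 * pi * cfg$freqs)
  support <- ceiling(4 * max(sigma_t) * cfg$fs)
  if (n < support) {
    stop("signal shorter than the longest wavelet support (", support, " samples)")
  }
  npad <- nextn(n + 2L * support, c(2, 3, 5))
  xf <- stats::fft(c(signal, numeric(npad - n)))
  # FFT bin frequencies in Hz (two-sided)
  fgrid <- (seq_len(npad) - 1L) / npad * cfg$fs
  fgrid[fgrid > cfg$fs / 2] <- fgrid[fgrid > cfg$fs / 2] - cfg$fs
  out <- matrix(0, length(cfg$freqs), n)
  for (i in seq_along(cfg$freqs)) {
    f0 <- cfg$freqs[i]
    sigma_f <- f0 / cfg$morlet_width
    win <- exp(-((fgrid - f0)^2) / (2 * sigma_f^2))
    # analytic (one-sided) response: suppress negative frequencies
    win[fgrid < 0] <- 0
    coefs <- stats::fft(xf * win, inverse = TRUE) / npad
    out[i, ] <- Mod(coefs[seq_len(n)])
  }
  attr(out, "edge_samples") <- pmin(ceiling(3 * sigma_t * cfg$fs), n)
  out
}

#' Epoch multichannel signals into feature tensors
#'
#' Maps a channels x samples recording to the tensor of epoch features
#' `N x n_freqs x n_time_bins x n_channels`: the wavelet power of each
#' channel is computed once over the whole recording, epochs start every
#' `step_seconds`, and within each epoch the power is averaged over
#' `n_time_bins` contiguous non-overlapping bins. The epoch count is
#' `floor((T - epoch) / step) + 1` for `T` total samples.
#'
#' @param signals Numeric matrix `channels x samples` (a vector is treated
#'   as one channel).
#' @param cfg An [epoch_config()].
#' @param n_channels Optional declared montage size; a mismatch with
#'   `nrow(signals)` is an error.
#' @return Numeric array `N x n_freqs x n_time_bins x n_channels` with
#'   attribute `epoch_start`: first-sample index of each epoch. Epoch `k`'s
#'   features end at sample `epoch_start[k] + epoch_samples - 1`; supervised
#'   responses should be aligned to that end time (causal decoding).
#' @export
epoch_features <- function(signals, cfg, n_channels = NULL) {
  stopifnot(inherits(cfg, "epoch_config"))
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1L)
  nch <- nrow(signals)
  if (!is.null(n_channels) && n_channels != nch) {
    stop("declared montage has ", n_channels, " channels but signals have ", nch)
  }
  nsamp <- ncol(signals)
  ep <- cfg$epoch_samples
  st <- cfg$step_samples
  if (nsamp < ep) stop("not enough samples for a single epoch")
  n_epochs <- (nsamp - ep) %/% st + 1L
  nf <- length(cfg$freqs)
  nb <- cfg$n_time_bins
  bin <- ep %/% nb
  out <- array(0, c(n_epochs, nf, nb, nch))
  starts <- (seq_len(n_epochs) - 1L) * st + 1L
  bin_grp <- rep(seq_len(nb), each = bin)
  for (ch in seq_len(nch)) {
    pw <- morlet_power(signals[ch, ], cfg)
    for (k in seq_len(n_epochs)) {
      seg <- pw[, starts[k]:(starts[k] + ep - 1L), drop = FALSE]
      # nf x nb matrix of bin means
      out[k, , , ch] <- t(rowsum(t(seg), bin_grp)) / bin
    }
  }
  attr(out, "epoch_start") <- starts
  out
}
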