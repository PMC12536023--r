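#' Spectral analysis configuration
#'
#' Settings for epoch segmentation and Welch spectral estimation.  The
#' defaults follow the analysis protocol the package implements: 5-s epochs
#' with 80% overlap, Hamming tapering, and a minimum of 10 epochs (50 s of
#' data) for a recording to enter the analysis.
#'
#' @param epoch_seconds Epoch length in seconds (> 0).
#' @param overlap_fraction Fraction of overlap between consecutive epochs,
#'   in `[0, 1)`.
#' @param window Taper name; only `"hamming"` is implemented.
#' @param min_epochs Minimum number of epochs required for analysis (>= 1).
#' @return An object of class `spectral_config`.
#' @examples
#' cfg <- spectral_config()
#' cfg$epoch_seconds
#' @export
spectral_config <- function(epoch_seconds = 5, overlap_fraction = 0.8,
                            window = "hamming", min_epochs = 10) {
  stopifnot(is.numeric(epoch_seconds), length(epoch_seconds) == 1L,
            epoch_seconds > 0,
            is.numeric(overlap_fraction), length(overlap_fraction) == 1L,
            overlap_fraction >= 0, overlap_fraction < 1,
            is.numeric(min_epochs), min_epochs >= 1)
  window <- match.arg(window, "hamming")
  # guard against step sizes that collapse to < 1 sample at any sane fs
  if (overlap_fraction > 0.999)
    stop("overlap_fraction too close to 1; epochs would not advance")
  structure(list(epoch_seconds = epoch_seconds,
                 overlap_fraction = overlap_fraction,
                 window = window,
                 min_epochs = as.integer(min_epochs)),
            class = "spectral_config")
}

#' Power spectrum container
#'
#' @param freqs Strictly increasing frequency grid in Hz.
#' @param power Nonnegative power values, same length as `freqs`.
#' @param n_epochs Number of epochs that contributed to the estimate.
#' @return An object of class `paf_psd` (also a list with elements `freqs`,
#'   `power`, `n_epochs`).
#' @export
paf_psd <- function(freqs, power, n_epochs = NA_integer_) {
  stopifnot(is.numeric(freqs), is.numeric(power),
            length(freqs) == length(power), length(freqs) > 0)
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (any(!is.finite(power)) || any(power < 0))
    stop("power must be finite and nonnegative")
  structure(list(freqs = as.numeric(freqs), power = as.numeric(power),
                 n_epochs = n_epochs),
            class = "paf_psd")
}

#' @export
print.paf_psd <- function(x, ...) {
  cat(sprintf("Power spectrum: %d bins, %.3g-%.3g Hz (spacing %.3g Hz)",
              length(x$freqs), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1]))
  if (!is.na(x$n_epochs)) cat(sprintf(", %d epochs", x$n_epochs))
  cat("\n")
  invisible(x)
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Segment a recording into overlapping epochs
#'
#' Cuts a continuous signal into epochs of `epoch_seconds` with the
#' configured overlap.  The start-to-start step is rounded to whole samples;
#' the number of epochs equals `floor((N - L)/step) + 1` for a recording of
#' `N` samples and epoch length `L` samples.
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @param cfg A [spectral_config()].
#' @return A numeric matrix with one epoch per column (`L` rows).
#' @examples
#' ep <- segment_into_epochs(sin(2 * pi * 10 * seq(0, 120, by = 1/500)),
#'                           fs = 500)
#' ncol(ep)  # 116 epochs for 120 s of data
#' @export
segment_into_epochs <- function(x, fs, cfg = spectral_config()) {
  stopifnot(is.numeric(x), is.numeric(fs), fs > 0)
  L <- round(cfg$epoch_seconds * fs)
  if (length(x) < L)
    stop(sprintf("recording too short: %d samples < one epoch of %d samples",
                 length(x), L))
  step <- max(1L, round(L * (1 - cfg$overlap_fraction)))
  starts <- seq.int(1L, length(x) - L + 1L, by = step)
  vapply(starts, function(s) x[s:(s + L - 1L)], numeric(L))
}

#' Minimum-epoch inclusion gate
#'
#' A recording must provide at least `cfg$min_epochs` epochs (by default 10,
#' i.e. 50 s of unique data at the default epoch length) to be analysed.
#'
#' @param epochs Epoch matrix from [segment_into_epochs()], or an epoch count.
#' @param cfg A [spectral_config()].
#' @return `TRUE` if the recording passes, `FALSE` if it must be excluded.
#' @export
enforce_minimum_epochs <- function(epochs, cfg = spectral_config()) {
  n <- if (is.matrix(epochs)) ncol(epochs) else as.integer(epochs)
  n >= cfg$min_epochs
}

#' Welch power spectral density
#'
#' Averages Hamming-tapered, one-sided periodograms of the supplied epochs.
#' Each epoch is mean-removed before tapering (no further detrending), and
#' the density normalisation includes the window power correction, so the
#' integral of the density over `[0, fs/2]` estimates the signal variance.
#' No zero-padding is applied: the bin spacing is exactly
#' `1 / epoch_seconds` Hz.
#'
#' @param epochs Epoch matrix (one epoch per column), e.g. from
#'   [segment_into_epochs()].
#' @param fs Sampling rate in Hz.
#' @param cfg A [spectral_config()] (used for the taper choice).
#' @return A [paf_psd()] with the zero-frequency bin removed.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 120, by = 1/500))
#' psd <- welch_psd(segment_into_epochs(x, 500), fs = 500)
#' psd$freqs[which.max(psd$power)]  # 10 Hz
#' @export
welch_psd <- function(epochs, fs, cfg = spectral_config()) {
  if (is.vector(epochs)) epochs <- matrix(epochs, ncol = 1)
  stopifnot(is.matrix(epochs), ncol(epochs) >= 1, fs > 0)
  L <- nrow(epochs)
  w <- hamming_window(L)
  scale <- 1 / (fs * sum(w^2))
  n_freq <- L %/% 2 + 1L
  acc <- numeric(n_freq)
  for (j in seq_len(ncol(epochs))) {
    seg <- epochs[, j]
    seg <- (seg - mean(seg)) * w
    spec <- abs(fft(seg)[seq_len(n_freq)])^2 * scale
    # one-sided: double everything except DC and (for even L) Nyquist
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[n_freq] <- 1
    acc <- acc + spec * dbl
  }
  pxx <- acc / ncol(epochs)
  freqs <- (seq_len(n_freq) - 1) * fs / L
  # drop the DC bin: zero frequency has no place on a log-frequency axis
  paf_psd(freqs[-1], pxx[-1], n_epochs = ncol(epochs))
}

#' Segment and compute a Welch spectrum in one call
#'
#' Convenience wrapper: [segment_into_epochs()] followed by [welch_psd()].
#' Fails if the recording does not meet the minimum-epoch gate.
#'
#' @inheritParams segment_into_epochs
#' @param enforce_gate If `TRUE` (default), error when fewer than
#'   `cfg$min_epochs` epochs are available.
#' @return A [paf_psd()].
#' @export
compute_psd <- function(x, fs, cfg = spectral_config(), enforce_gate = TRUE) {
  ep <- segment_into_epochs(x, fs, cfg)
  if (enforce_gate && !enforce_minimum_epochs(ep, cfg))
    stop(sprintf("recording excluded: %d epochs < minimum of %d",
                 ncol(ep), cfg$min_epochs))
  welch_psd(ep, fs, cfg)
}
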