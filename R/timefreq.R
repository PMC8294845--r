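#' Hann-tapered complex wavelet
#'
#' Builds the fixed-length complex kernel used for single-trial
#' time-frequency decomposition: a complex exponential at frequency `f`
#' multiplied by a Hann taper over a fixed `duration` (default 0.5 s, the
#' same length at every frequency, so spectral bandwidth is constant while
#' the number of cycles grows with `f`), normalized to unit energy so power
#' is comparable across frequencies.
#'
#' @param f wavelet center frequency, Hz (> 0).
#' @param fs sampling rate, Hz.
#' @param duration kernel length in seconds.
#' @return complex vector of length `round(duration * fs)`; attributes `f`,
#'   `fs`, `duration`.
#' @export
#' @examples
#' k <- build_wavelet(10, fs = 512)
#' length(k)  # 256
build_wavelet <- function(f, fs, duration = 0.5) {
  if (!is.numeric(f) || f <= 0) stop("frequency must be positive", call. = FALSE)
  n <- round(duration * fs)
  if (n < 8) stop("duration * fs must be at least 8 samples", call. = FALSE)
  t <- (seq_len(n) - (n + 1) / 2) / fs # centred on 0, spans +/- duration/2
  k <- hann_window(n) * exp(1i * 2 * pi * f * t)
  k <- k / sqrt(sum(Mod(k)^2))
  attributes(k) <- list(f = f, fs = fs, duration = duration)
  k
}

#' Single-trial time-frequency power
#'
#' Convolves every trial and EEG channel with the Hann-tapered complex
#' wavelet of each frequency and takes the squared magnitude, yielding raw
#' single-trial power (induced plus evoked; no baseline correction, no
#' averaging before the magnitude). The convolution is evaluated directly on
#' the output time grid — multiples of `1 / out_rate` seconds from stimulus
#' onset spanning `crop` — which implements the resampling to 64 Hz used for
#' decoding. The epoch must extend at least half a wavelet beyond the crop on
#' both sides so every output sample is free of edge effects.
#'
#' @param epochs an `eeg_epochs` object.
#' @param freqs analysis frequencies, Hz (default 2-30 Hz in 2 Hz steps).
#' @param crop output window `c(t_lo, t_hi)` in seconds (closed; grid points
#'   `k / out_rate` falling inside it are produced — the default yields 71
#'   samples from -93.75 ms to 1000 ms).
#' @param out_rate output sampling rate, Hz.
#' @param duration wavelet length, seconds.
#' @return a `tf_power` object: `power` array trials x channels x
#'   frequencies x times (microvolts squared, EEG channels only), `freqs`,
#'   `times`, `channels`, `events`, and provenance fields.
#' @export
compute_tf_power <- function(epochs, freqs = seq(2, 30, by = 2),
                             crop = c(-0.1, 1.0), out_rate = 64,
                             duration = 0.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$srate
  k_lo <- ceiling(crop[1] * out_rate - 1e-9)
  k_hi <- floor(crop[2] * out_rate + 1e-9)
  t_out <- (k_lo:k_hi) / out_rate
  n_kern <- round(duration * fs)
  half_lo <- floor((n_kern - 1) / 2)
  half_hi <- n_kern - 1 - half_lo
  # centre sample of each output time in the epoch's sample grid
  centers <- round((t_out - epochs$times[1]) * fs) + 1
  n_samp <- length(epochs$times)
  if (any(centers - half_lo < 1) || any(centers + half_hi > n_samp))
    stop("epoch too short for an edge-free crop window", call. = FALSE)

  eeg <- channel_idx(epochs, "eeg")
  n_tr <- dim(epochs$voltages)[1]
  n_ch <- length(eeg)
  n_f <- length(freqs)
  n_t <- length(t_out)
  # samples x (trial, channel) matrix, trial varying fastest within channel
  x <- matrix(aperm(epochs$voltages[, eeg, , drop = FALSE], c(3, 1, 2)),
              nrow = n_samp)
  # one stacked correlation matrix: row (fi, ti) holds the conjugate wavelet
  # of frequency fi aligned on output time ti, so power for every bin is two
  # real BLAS products per data chunk
  kr <- matrix(0, n_f * n_t, n_samp)
  ki <- matrix(0, n_f * n_t, n_samp)
  for (fi in seq_len(n_f)) {
    kc <- Conj(unclass(build_wavelet(freqs[fi], fs, duration)))
    for (ti in seq_len(n_t)) {
      cols <- (centers[ti] - half_lo):(centers[ti] + half_hi)
      row <- (fi - 1) * n_t + ti
      kr[row, cols] <- Re(kc)
      ki[row, cols] <- Im(kc)
    }
  }
  pw <- array(NA_real_, dim = c(n_tr, n_ch, n_f, n_t))
  ch_chunk <- max(1, floor(4e6 / (n_tr * n_f * n_t)))
  for (lo in seq(1, n_ch, by = ch_chunk)) {
    chs <- lo:min(lo + ch_chunk - 1, n_ch)
    cols <- ((chs[1] - 1) * n_tr + 1):(chs[length(chs)] * n_tr)
    xs <- x[, cols, drop = FALSE]
    p <- (kr %*% xs)^2 + (ki %*% xs)^2 # (fi,ti) bins x (trial, channel)
    pw[, chs, , ] <- aperm(array(p, c(n_t, n_f, n_tr, length(chs))),
                           c(3, 4, 2, 1))
  }
  structure(list(power = pw, freqs = freqs, times = t_out,
                 channels = epochs$layout$name[eeg], events = epochs$events,
                 wavelet_duration = duration, taper = "hann",
                 normalization = "unit-energy", srate_in = fs,
                 out_rate = out_rate),
            class = "tf_power")
}

#' @export
print.tf_power <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<tf_power> %d trials x %d channels x %d freqs (%g-%g Hz) x %d times (%.4g to %.4g s)\n",
    d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4], min(x$times), max(x$times)))
  invisible(x)
}
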