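# shared fixtures, all generated in code

# a small deterministic epochs object with known content
toy_epochs <- function(n_trials = 4, n_eeg = 3, fs = 512, t0 = -1, t1 = 2,
                       fill = 0) {
  lay <- eeg_layout_64()
  lay <- rbind(lay[lay$type == "eeg", ][seq_len(n_eeg), ],
               lay[lay$type != "eeg", ])
  times <- seq(t0, t1 - 1 / fs, by = 1 / fs)
  v <- array(fill, dim = c(n_trials, nrow(lay), length(times)))
  eeg_epochs(v, lay, times, fs)
}

# fast low-channel synthetic config for pipeline-level tests
quick_config <- function(n_trials = 48, n_eeg = 16, amplitude = 6, seed = 1,
                         ...) {
  synthetic_config(
    n_trials = n_trials, n_eeg_channels = n_eeg,
    effects = list(effect_spec(
      amplitude = c(congruent = 0, incongruent = amplitude))),
    blink_prob = 0, hv_prob = 0, seed = seed, ...)
}

# mean band power in a time window at given channels (independent oracle for
# the injected-effect checks: plain FFT band energy, no wavelets)
band_power_oracle <- function(epochs, channels, band, window) {
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  fs <- epochs$srate
  n <- sum(sel)
  fax <- (seq_len(n) - 1) * fs / n
  keep <- fax >= band[1] & fax <= band[2]
  vapply(seq_len(dim(epochs$voltages)[1]), function(i) {
    mean(vapply(channels, function(ch) {
      sp <- Mod(stats::fft(epochs$voltages[i, ch, sel]))^2
      sum(sp[keep]) / n
    }, numeric(1)))
  }, numeric(1))
}
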