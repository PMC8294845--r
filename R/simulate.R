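#' Specification of an injected class effect
#'
#' Describes one oscillatory effect the simulator injects into the EEG: which
#' trial factor drives it, the frequency band and post-stimulus window of the
#' burst, its scalp topography, and the burst amplitude per factor level. On
#' every trial a band-limited sinusoid (carrier drawn uniformly from `band`,
#' random phase unless `phase_locked`) is Hann-enveloped over `window`, scaled
#' by the level's amplitude, projected onto the topography and added to the
#' EEG channels. A level with amplitude 0 receives no burst, so amplitude
#' differences between levels are what the decoders can pick up.
#'
#' @param feature `"congruency"`, `"content"` or `"location"`.
#' @param band `c(f_lo, f_hi)` in Hz, `f_lo <= f_hi`.
#' @param window `c(t_on, t_off)` in seconds post-stimulus, `t_on < t_off`.
#' @param topography unit-norm per-EEG-channel weights (see
#'   [gaussian_topography()]) or a preset name.
#' @param amplitude named numeric, burst amplitude in microvolts per factor
#'   level (e.g. `c(congruent = 0, incongruent = 6)`).
#' @param phase_locked logical; if `TRUE` the burst phase is identical across
#'   trials (an evoked, time-domain-decodable effect), otherwise phase is
#'   random per trial (induced power effect).
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(feature = c("congruency", "content", "location"),
                        band = c(4, 8), window = c(0.1, 0.7),
                        topography = "midfrontal",
                        amplitude = c(congruent = 0, incongruent = 6),
                        phase_locked = FALSE) {
  feature <- match.arg(feature)
  stopifnot(length(band) == 2, band[1] <= band[2], band[1] > 0,
            length(window) == 2, window[1] < window[2],
            is.numeric(amplitude), !is.null(names(amplitude)))
  structure(list(feature = feature, band = band, window = window,
                 topography = topography, amplitude = amplitude,
                 phase_locked = phase_locked),
            class = "effect_spec")
}

#' Configuration of a synthetic experiment
#'
#' Collects every constant the generators need. Defaults follow the emulated
#' study designs: 64 EEG channels sampled at 512 Hz, epochs spanning -1 to 2 s
#' around stimulus onset, 1/f background noise, a theta-band midfrontal
#' congruency effect, sparse blink and high-voltage artifacts, and a 30 ms
#' behavioral conflict effect.
#'
#' @param n_participants simulated cohort size.
#' @param n_trials trials per session (1200 for the first content
#'   discrimination task's full session; smaller values are typical for
#'   simulation studies).
#' @param task one of [task_ids()].
#' @param sampling_rate Hz.
#' @param n_eeg_channels number of EEG channels (<= 64; a subset of the
#'   standard layout is used when fewer).
#' @param epoch_window `c(t_min, t_max)` of the generated epoch, seconds.
#' @param effects list of [effect_spec()] objects.
#' @param noise_exponent 1/f^alpha exponent of the background noise.
#' @param noise_amp_uv per-channel noise standard deviation, microvolts.
#' @param alpha_amp_uv amplitude of an optional 10 Hz posterior alpha rhythm
#'   (0 disables it).
#' @param blink_prob per-epoch blink probability (blinks land within the
#'   0-800 ms artifact-screening window on the VEOG channel).
#' @param blink_amp_uv blink peak amplitude.
#' @param hv_prob per-epoch probability of a broadband high-voltage transient
#'   on a random EEG channel.
#' @param hv_amp_uv transient peak amplitude.
#' @param behavior a [behavior_params()] list.
#' @param seed master seed for the dataset.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 12, n_trials = 400,
                             task = "content_discrimination_1",
                             sampling_rate = 512, n_eeg_channels = 64,
                             epoch_window = c(-1, 2),
                             effects = list(effect_spec()),
                             noise_exponent = 1, noise_amp_uv = 10,
                             alpha_amp_uv = 0,
                             blink_prob = 0.05, blink_amp_uv = 200,
                             hv_prob = 0.02, hv_amp_uv = 350,
                             behavior = behavior_params(), seed = 1) {
  task <- match.arg(task, task_ids())
  .check_scalar(n_trials, "n_trials", lower = 1)
  .check_scalar(sampling_rate, "sampling_rate", lower = 1)
  .check_scalar(n_eeg_channels, "n_eeg_channels", lower = 2, upper = 64)
  for (p in c(blink_prob, hv_prob))
    .check_scalar(p, "artifact probability", lower = 0, upper = 1)
  structure(list(n_participants = n_participants, n_trials = n_trials,
                 task = task, sampling_rate = sampling_rate,
                 n_eeg_channels = n_eeg_channels, epoch_window = epoch_window,
                 effects = effects, noise_exponent = noise_exponent,
                 noise_amp_uv = noise_amp_uv, alpha_amp_uv = alpha_amp_uv,
                 blink_prob = blink_prob, blink_amp_uv = blink_amp_uv,
                 hv_prob = hv_prob, hv_amp_uv = hv_amp_uv,
                 behavior = behavior, seed = seed),
            class = "synthetic_config")
}

# internal: layout restricted to the first n EEG channels (evenly spaced over
# the cap so reduced montages still cover the scalp) plus all peripherals
.config_layout <- function(config) {
  lay <- eeg_layout_64()
  eeg <- which(lay$type == "eeg")
  keep <- eeg[round(seq(1, length(eeg), length.out = config$n_eeg_channels))]
  lay[c(keep, which(lay$type != "eeg")), , drop = FALSE]
}

# internal: one trial-matrix (samples x channels) of 1/f^alpha noise with
# exact expected per-channel sd `amp`
.pink_noise <- function(n_samples, n_channels, fs, alpha, amp) {
  n <- n_samples
  freqs <- seq_len(floor((n - 1) / 2)) * fs / n
  scale <- freqs^(-alpha / 2)
  nf <- length(freqs)
  # complex spectrum, Hermitian-symmetric so the inverse FFT is real
  z <- matrix(complex(real = rnorm(nf * n_channels),
                      imaginary = rnorm(nf * n_channels)) * scale,
              nrow = nf)
  spec <- matrix(0i, nrow = n, ncol = n_channels)
  spec[2:(nf + 1), ] <- z
  spec[n:(n - nf + 1), ] <- Conj(z)
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  # Var(x_t) = (1/n^2) * sum_k 2*scale_k^2 (re+im each unit variance, two
  # Hermitian halves) -> rescale to the requested sd
  target_var <- 2 * 2 * sum(scale^2) / n^2
  x * (amp / sqrt(target_var))
}

#' Generate multichannel EEG epochs for a design
#'
#' Builds one participant-session of epoched EEG: per trial, 1/f background
#' noise on every channel, plus each configured effect's oscillatory burst on
#' the EEG channels, plus blink transients (positive half-cosine, 300-500 ms)
#' on the VEOG channel and broadband high-voltage transients on random EEG
#' channels. Returns the epochs together with a ground-truth record (injected
#' specs and per-trial artifact flags) for recovery scoring.
#'
#' @param design a `DesignTable` from [generate_design()].
#' @param config a [synthetic_config()].
#' @param seed integer seed; identical inputs give identical arrays.
#' @return `list(epochs = eeg_epochs, truth = list(...))`.
#' @export
generate_eeg <- function(design, config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  n_trials <- nrow(design)
  if (n_trials == 0) stop("design is empty", call. = FALSE)
  fs <- config$sampling_rate
  tw <- config$epoch_window
  times <- seq(tw[1], tw[2] - 1 / fs, by = 1 / fs)
  n_samp <- length(times)
  layout <- .config_layout(config)
  n_chan <- nrow(layout)
  eeg_ch <- which(layout$type == "eeg")
  veog_ch <- which(layout$type == "veog")
  if (length(veog_ch) == 0) stop("layout must contain a VEOG channel")

  # resolve effect topographies/levels once, validating against this layout
  effects <- lapply(config$effects, function(ef) {
    topo <- ef$topography
    if (is.character(topo)) topo <- gaussian_topography(layout, topo)
    if (length(topo) != length(eeg_ch))
      stop("topography length must match the number of EEG channels",
           call. = FALSE)
    if (ef$window[1] < times[1] || ef$window[2] > times[n_samp])
      stop("effect window outside epoch", call. = FALSE)
    col <- switch(ef$feature, congruency = "congruency",
                  content = "sound_content", location = "sound_location")
    lev <- design[[col]]
    if (!all(unique(lev) %in% names(ef$amplitude)))
      stop("amplitude must name every level of ", ef$feature, call. = FALSE)
    list(spec = ef, topo = topo, amp = unname(ef$amplitude[lev]))
  })

  set.seed(seed)
  volt <- array(0, dim = c(n_trials, n_chan, n_samp))
  blink <- runif(n_trials) < config$blink_prob
  hv <- runif(n_trials) < config$hv_prob

  # background noise, generated in chunks of trials for FFT efficiency
  chunk <- max(1, floor(1024 / n_chan))
  for (lo in seq(1, n_trials, by = chunk)) {
    idx <- lo:min(lo + chunk - 1, n_trials)
    x <- .pink_noise(n_samp, n_chan * length(idx), fs, config$noise_exponent,
                     config$noise_amp_uv) # samples x (chan, trial)
    volt[idx, , ] <- aperm(array(x, c(n_samp, n_chan, length(idx))), c(3, 2, 1))
  }

  topo_a <- if (config$alpha_amp_uv > 0) gaussian_topography(layout, "occipital")
  for (i in seq_len(n_trials)) {
    if (config$alpha_amp_uv > 0) {
      wave <- config$alpha_amp_uv * sin(2 * pi * 10 * times + runif(1, 0, 2 * pi))
      volt[i, eeg_ch, ] <- volt[i, eeg_ch, ] + topo_a %o% wave
    }
    for (ef in effects) {
      a <- ef$amp[i]
      if (a == 0) next
      f0 <- if (ef$spec$band[1] == ef$spec$band[2]) ef$spec$band[1] else
        runif(1, ef$spec$band[1], ef$spec$band[2])
      phi <- if (ef$spec$phase_locked) 0 else runif(1, 0, 2 * pi)
      w <- ef$spec$window
      sel <- which(times >= w[1] & times <= w[2])
      burst <- a * hann_window(length(sel)) *
        sin(2 * pi * f0 * (times[sel] - w[1]) + phi)
      volt[i, eeg_ch, sel] <- volt[i, eeg_ch, sel] + ef$topo %o% burst
    }
    if (blink[i]) {
      on <- runif(1, 0, 0.3); dur <- runif(1, 0.3, 0.5)
      sel <- which(times >= on & times <= on + dur)
      u <- seq(0, 1, length.out = length(sel))
      volt[i, veog_ch[1], sel] <- volt[i, veog_ch[1], sel] +
        config$blink_amp_uv * sin(pi * u)
    }
    if (hv[i]) {
      ch <- sample(eeg_ch, 1)
      on <- runif(1, 0, 0.7)
      sel <- which(times >= on & times <= on + 0.1)
      u <- seq(0, 1, length.out = length(sel))
      volt[i, ch, sel] <- volt[i, ch, sel] +
        config$hv_amp_uv * sin(pi * u) * sample(c(-1, 1), 1) *
        (1 + 0.2 * rnorm(length(sel)))
    }
  }

  epochs <- eeg_epochs(volt, layout, times, fs, events = design)
  truth <- list(effects = config$effects, blink = blink, high_voltage = hv,
                behavior = config$behavior, seed = seed)
  list(epochs = epochs, truth = truth)
}

#' Simulate one full participant-session
#'
#' Convenience wrapper chaining [generate_design()], [generate_behavior()] and
#' [generate_eeg()], with per-stage seeds derived from the config master seed
#' and the participant id via [derive_seed()].
#'
#' @param config a [synthetic_config()].
#' @param participant participant index (1-based).
#' @return `list(design, behavior, epochs, truth)`.
#' @export
simulate_participant <- function(config, participant = 1) {
  d <- generate_design(config$task, config$n_trials,
                       seed = derive_seed(config$seed, "design", participant))
  b <- generate_behavior(d, config$task, config$behavior,
                         seed = derive_seed(config$seed, "behavior", participant))
  ee <- generate_eeg(d, config,
                     seed = derive_seed(config$seed, "eeg", participant))
  list(design = d, behavior = b, epochs = ee$epochs, truth = ee$truth)
}
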