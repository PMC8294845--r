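#' Zero-phase band-pass filter
#'
#' Filters every channel of every epoch with the preprocessing band-pass
#' (default 0.01-50 Hz). The realization is explicit mean removal (the
#' sub-0.1 Hz high-pass edge is far below the resolution of a 3 s epoch, so
#' the DC/drift rejection it encodes is implemented exactly) followed by
#' zero-phase Butterworth filtering — an order-2 high-pass at `lo` cascaded
#' with an order-4 low-pass at `hi` — applied in the frequency domain through
#' the squared magnitude response of the designed digital filters (the
#' magnitude a forward-backward application realizes, with exactly zero phase
#' shift). Attenuation exceeds 20 dB one octave beyond each cutoff.
#'
#' @param epochs an `eeg_epochs` object.
#' @param lo,hi cutoff frequencies, Hz; `lo < hi < srate/2`.
#' @return the filtered `eeg_epochs`.
#' @export
bandpass_filter <- function(epochs, lo = 0.01, hi = 50) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$srate
  if (!(lo < hi)) stop("lo must be below hi", call. = FALSE)
  if (hi >= fs / 2) stop("hi must be below the Nyquist frequency", call. = FALSE)
  n <- dim(epochs$voltages)[3]
  gain <- .bandpass_gain(n, fs, lo, hi)
  v <- epochs$voltages
  for (i in seq_len(dim(v)[1])) {
    x <- t(v[i, , ]) # samples x channels
    x <- sweep(x, 2, colMeans(x))
    xf <- stats::mvfft(x) * gain
    v[i, , ] <- t(Re(stats::mvfft(xf, inverse = TRUE)) / n)
  }
  epochs$voltages <- v
  epochs
}

# internal: squared-magnitude (zero-phase) response of the Butterworth
# cascade, evaluated on the length-n FFT grid
.bandpass_gain <- function(n, fs, lo, hi) {
  bh <- signal::butter(2, lo / (fs / 2), type = "high")
  bl <- signal::butter(4, hi / (fs / 2), type = "low")
  w <- 2 * pi * (0:(n - 1)) / n # digital frequency of each FFT bin
  resp <- function(flt) {
    z <- exp(-1i * w)
    num <- Reduce(function(acc, b) acc * z + b, flt$b, accumulate = FALSE)
    den <- Reduce(function(acc, a) acc * z + a, flt$a, accumulate = FALSE)
    num / den
  }
  Mod(resp(bh))^2 * Mod(resp(bl))^2
}

#' Re-reference to the average of reference channels
#'
#' Subtracts the mean of the named reference channels (typically the two
#' earlobe electrodes) from every EEG channel, sample-wise. Reference and
#' other peripheral channels are retained unchanged and stay flagged in the
#' layout.
#'
#' @param epochs an `eeg_epochs` object.
#' @param ref_channels channel names to average; defaults to the layout's
#'   `type == "ref"` channels.
#' @return the re-referenced `eeg_epochs`.
#' @export
rereference <- function(epochs, ref_channels = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(ref_channels))
    ref_channels <- epochs$layout$name[epochs$layout$type == "ref"]
  miss <- setdiff(ref_channels, epochs$layout$name)
  if (length(miss)) stop("missing reference channel: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  ref_idx <- match(ref_channels, epochs$layout$name)
  eeg_idx <- which(epochs$layout$type == "eeg")
  v <- epochs$voltages
  refmean <- apply(v[, ref_idx, , drop = FALSE], c(1, 3), mean) # trials x samples
  for (j in eeg_idx) v[, j, ] <- v[, j, ] - refmean
  epochs$voltages <- v
  epochs
}

#' Cut epochs out of a continuous recording
#'
#' Extracts one epoch per event from a continuous multichannel recording,
#' using a half-open window `[t_min, t_max)` sample-aligned to the event
#' (time 0 is the event sample itself).
#'
#' @param continuous numeric matrix, channels x samples.
#' @param events integer vector of event sample indices (1-based).
#' @param layout channel table matching the rows of `continuous`.
#' @param srate sampling rate, Hz.
#' @param t_min,t_max epoch window in seconds relative to each event.
#' @param event_table optional data.frame of per-event labels.
#' @return an `eeg_epochs` object with `dim(...)[3] == (t_max - t_min) * srate`.
#' @export
segment_epochs <- function(continuous, events, layout, srate,
                           t_min = -1, t_max = 2, event_table = NULL) {
  stopifnot(is.matrix(continuous), t_min < t_max)
  n_off <- round(t_min * srate)
  n_len <- round((t_max - t_min) * srate)
  starts <- events + n_off
  if (any(starts < 1) || any(starts + n_len - 1 > ncol(continuous)))
    stop("epoch window exceeds recording bounds", call. = FALSE)
  n_ev <- length(events)
  v <- array(0, dim = c(n_ev, nrow(continuous), n_len))
  for (i in seq_len(n_ev))
    v[i, , ] <- continuous[, starts[i]:(starts[i] + n_len - 1)]
  times <- (n_off + seq_len(n_len) - 1) / srate
  eeg_epochs(v, layout, times, srate, events = event_table)
}

#' Two-pass amplitude-based artifact rejection
#'
#' Pass 1 drops epochs whose VEOG signal exceeds `veog_thresh_uv` in absolute
#' value anywhere in the screening window (blinks); pass 2 drops remaining
#' epochs in which any EEG channel exceeds `eeg_thresh_uv` in the same window
#' (high-voltage artifacts). Excursions outside the screening window are
#' ignored. The report accounts per-pass fractions relative to the total
#' epoch count, mirroring the sequential bookkeeping of the procedure.
#'
#' @param epochs an `eeg_epochs` object with a VEOG channel.
#' @param veog_thresh_uv,eeg_thresh_uv rejection thresholds, microvolts.
#' @param window screening window in seconds post-stimulus.
#' @return `list(epochs = kept eeg_epochs, report = list(trials = data.frame(
#'   trial, keep, reason), fraction_blink, fraction_voltage,
#'   fraction_total))`.
#' @export
reject_artifacts <- function(epochs, veog_thresh_uv = 100, eeg_thresh_uv = 300,
                             window = c(0, 0.8)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  veog <- channel_idx(epochs, "veog")
  if (length(veog) == 0) stop("no VEOG channel present", call. = FALSE)
  eeg <- channel_idx(epochs, "eeg")
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  n <- dim(epochs$voltages)[1]

  veog_max <- apply(abs(epochs$voltages[, veog, sel, drop = FALSE]), 1, max)
  is_blink <- veog_max > veog_thresh_uv
  eeg_max <- apply(abs(epochs$voltages[, eeg, sel, drop = FALSE]), 1, max)
  is_hv <- !is_blink & eeg_max > eeg_thresh_uv

  reason <- rep(NA_character_, n)
  reason[is_blink] <- "blink"
  reason[is_hv] <- "voltage"
  keep <- !(is_blink | is_hv)
  report <- list(
    trials = data.frame(trial = seq_len(n), keep = keep, reason = reason,
                        stringsAsFactors = FALSE),
    fraction_blink = mean(is_blink),
    fraction_voltage = mean(is_hv),
    fraction_total = mean(!keep)
  )
  list(epochs = .subset_epochs(epochs, which(keep)), report = report)
}

#' Screen participants on rejected-trial fractions
#'
#' Excludes participants whose fraction of rejected epochs lies more than
#' three standard deviations above the group mean (mean and SD computed over
#' all participants, candidates included). With fewer than three participants
#' screening is skipped with a warning; with zero spread nobody is excluded.
#'
#' @param rejection_fractions named numeric vector of per-participant
#'   rejected fractions in `[0, 1]`.
#' @param n_sd exclusion threshold in standard deviations.
#' @return integer indices of excluded participants (possibly empty).
#' @export
screen_participants <- function(rejection_fractions, n_sd = 3) {
  stopifnot(is.numeric(rejection_fractions))
  if (length(rejection_fractions) < 3) {
    warning("fewer than 3 participants; screening skipped")
    return(integer(0))
  }
  m <- mean(rejection_fractions)
  s <- sd(rejection_fractions)
  if (s == 0) return(integer(0))
  which(rejection_fractions > m + n_sd * s)
}

#' Select trials for behavioral statistics or decoding
#'
#' Applies the trial-selection rules: for behavioral statistics, trials with
#' RT below 100 ms or above 1500 ms are excluded, as are missed trials
#' (except in the oddball task, where non-responses are valid
#' correct rejections). For decoding, the auditory discrimination tasks keep
#' correct trials only; the volume-oddball task keeps correct rejections only
#' (no oddballs, no false alarms); the visual RDM tasks keep all trials.
#'
#' @param behavior a `BehavioralTable`.
#' @param task task id.
#' @param purpose `"behavior_stats"` or `"decoding"`.
#' @param rt_min_ms,rt_max_ms RT exclusion bounds for behavioral statistics.
#' @return integer vector of kept trial indices.
#' @export
select_trials <- function(behavior, task,
                          purpose = c("behavior_stats", "decoding"),
                          rt_min_ms = 100, rt_max_ms = 1500) {
  purpose <- match.arg(purpose)
  task <- match.arg(task, task_ids())
  n <- nrow(behavior)
  if (purpose == "behavior_stats") {
    bad_rt <- !is.na(behavior$rt_ms) &
      (behavior$rt_ms < rt_min_ms | behavior$rt_ms > rt_max_ms)
    missed <- is.na(behavior$rt_ms)
    if (task == "volume_oddball") {
      keep <- !bad_rt # non-responses are meaningful in go/no-go
    } else {
      keep <- !bad_rt & !missed
    }
  } else {
    keep <- switch(task,
      content_discrimination_1 = ,
      content_discrimination_2 = ,
      location_discrimination = behavior$correct,
      volume_oddball = behavior$correct & !behavior$oddball,
      vertical_rdm = ,
      horizontal_rdm = rep(TRUE, n))
  }
  which(keep)
}

#' Balance class counts by random undersampling
#'
#' Undersamples the majority class(es) to the minimum class count. When a
#' `cells` factor is supplied (typically the content-by-location cell), all
#' cells are equalized jointly so that every decoded contrast
#' (congruency, content, location) sees balanced confounds.
#'
#' @param labels class label per trial.
#' @param seed integer seed (undersampling is random but reproducible).
#' @param cells optional finer stratification factor to balance instead.
#' @return sorted integer vector of kept trial indices.
#' @export
balance_classes <- function(labels, seed = 1, cells = NULL) {
  strata <- if (is.null(cells)) labels else cells
  if (!is.factor(strata)) strata <- factor(strata)
  counts <- table(strata) # zero counts of empty factor levels are kept
  strata <- as.character(strata)
  if (any(counts == 0) || length(counts) < 2)
    stop("every class must contain at least one trial", call. = FALSE)
  m <- min(counts)
  set.seed(seed)
  kept <- unlist(lapply(names(counts), function(s) {
    idx <- which(strata == s)
    if (length(idx) > m) sample(idx, m) else idx
  }))
  sort(kept)
}
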