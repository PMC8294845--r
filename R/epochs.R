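#' Construct an epoched-EEG container
#'
#' The package's in-memory container for epoched data: a numeric array of
#' voltages (microvolts) of dimension trials x channels x samples, the channel
#' layout table, the time axis in seconds relative to stimulus onset, the
#' sampling rate and the per-trial event table.
#'
#' @param voltages numeric array, trials x channels x samples, in microvolts.
#' @param layout channel table (see [eeg_layout_64()]); `nrow(layout)` must
#'   equal `dim(voltages)[2]`.
#' @param times numeric vector of sample times in seconds, length
#'   `dim(voltages)[3]`.
#' @param srate sampling rate, Hz.
#' @param events data.frame with one row per trial (may have zero columns).
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(voltages, layout, times, srate, events = NULL) {
  stopifnot(length(dim(voltages)) == 3)
  d <- dim(voltages)
  if (nrow(layout) != d[2]) stop("layout rows must match channel dimension")
  if (length(times) != d[3]) stop("times must match sample dimension")
  if (is.null(events)) events <- data.frame(row.names = seq_len(d[1]))
  if (nrow(events) != d[1]) stop("events rows must match trial dimension")
  dimnames(voltages) <- list(NULL, layout$name, NULL)
  structure(list(voltages = voltages, layout = layout, times = times,
                 srate = srate, events = events),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$voltages)
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
    d[1], d[2], d[3], x$srate, min(x$times), max(x$times)))
  cat(sprintf("  channels: %d EEG + %d peripheral\n",
              sum(x$layout$type == "eeg"), sum(x$layout$type != "eeg")))
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$voltages)

#' Subset epochs by trial index
#'
#' Returns a new `eeg_epochs` containing the selected trials, with the event
#' table kept in register.
#'
#' @param epochs an `eeg_epochs` object.
#' @param idx integer trial indices.
#' @return the subsetted `eeg_epochs`.
#' @export
subset_epochs <- function(epochs, idx) {
  eeg_epochs(epochs$voltages[idx, , , drop = FALSE], epochs$layout,
             epochs$times, epochs$srate,
             epochs$events[idx, , drop = FALSE])
}

.subset_epochs <- subset_epochs # internal alias

#' Indices of channels by type
#' @param epochs an `eeg_epochs` object.
#' @param type a channel type in the layout (`"eeg"`, `"veog"`, ...).
#' @return integer channel indices.
#' @export
channel_idx <- function(epochs, type = "eeg") which(epochs$layout$type == type)

#' Write / read an epoched dataset
#'
#' Serializes the voltage array alongside a JSON sidecar holding the channel
#' table, time axis, sampling rate and event table, so a dataset on disk is
#' self-describing. `path` is a prefix; `<path>.rds` and `<path>.json` are
#' written.
#'
#' @param epochs an `eeg_epochs` object.
#' @param path file path prefix.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   restored `eeg_epochs`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  saveRDS(epochs$voltages, paste0(path, ".rds"))
  meta <- list(layout = epochs$layout, times = epochs$times,
               srate = epochs$srate, events = epochs$events)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  v <- readRDS(paste0(path, ".rds"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ev <- as.data.frame(meta$events, stringsAsFactors = FALSE)
  eeg_epochs(v, as.data.frame(meta$layout), as.numeric(meta$times),
             meta$srate, ev)
}
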