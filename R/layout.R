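#' Standard 64-channel scalp layout with peripheral channels
#'
#' Builds the channel table used by the simulator: 64 EEG electrodes laid out
#' on a unit head disk following the extended 10-10 naming scheme (the montage
#' of a standard 64-channel BioSemi cap), plus four peripheral channels — a
#' vertical and a horizontal EOG and two earlobe reference electrodes.
#' Positions are schematic 2-D projections (x: left negative, right positive;
#' y: anterior positive) adequate for topography templates and topographical
#' plots; they are not digitized coordinates.
#'
#' @return a data.frame with columns `name`, `x`, `y` and `type`
#'   (`"eeg"`, `"veog"`, `"heog"` or `"ref"`); 68 rows.
#' @export
#' @examples
#' lay <- eeg_layout_64()
#' table(lay$type)
eeg_layout_64 <- function() {
  rows <- list(
    list(y = 0.90, names = c("Fp1", "Fpz", "Fp2")),
    list(y = 0.72, names = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.54, names = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8")),
    list(y = 0.27, names = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8")),
    list(y = 0.00, names = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8")),
    list(y = -0.27, names = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8")),
    list(y = -0.54, names = c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10")),
    list(y = -0.72, names = c("PO7", "PO3", "POz", "PO4", "PO8")),
    list(y = -0.90, names = c("O1", "Oz", "O2")),
    list(y = -1.00, names = "Iz")
  )
  tabs <- lapply(rows, function(r) {
    k <- length(r$names)
    # spread electrodes across the head width available at this y
    half <- if (k == 1) 0 else sqrt(max(1.1^2 - r$y^2, 0.04))
    x <- if (k == 1) 0 else seq(-half, half, length.out = k)
    data.frame(name = r$names, x = x, y = r$y, type = "eeg",
               stringsAsFactors = FALSE)
  })
  eeg <- do.call(rbind, tabs)
  stopifnot(nrow(eeg) == 64)
  periph <- data.frame(
    name = c("VEOG", "HEOG", "M1", "M2"),
    x = c(0.35, 0.0, -1.30, 1.30),
    y = c(1.15, 1.25, 0.0, 0.0),
    type = c("veog", "heog", "ref", "ref"),
    stringsAsFactors = FALSE
  )
  out <- rbind(eeg, periph)
  rownames(out) <- NULL
  out
}

#' Gaussian scalp topography template
#'
#' Unit-norm per-channel weight vector over the EEG channels of a layout,
#' a 2-D Gaussian centred on a named scalp region (or explicit coordinates).
#' Used as the spatial projection of an injected effect.
#'
#' @param layout channel table from [eeg_layout_64()].
#' @param center one of `"midfrontal"`, `"left_temporal"`, `"right_temporal"`,
#'   `"occipital"`, `"central"`, or a numeric `c(x, y)`.
#' @param sigma Gaussian width in layout units (head radius approximately 1).
#' @return numeric weight vector, one entry per EEG channel, unit L2 norm,
#'   named by channel.
#' @export
#' @examples
#' topo <- gaussian_topography(eeg_layout_64(), "midfrontal")
#' names(which.max(topo))  # a frontocentral midline electrode
gaussian_topography <- function(layout, center = "midfrontal", sigma = 0.35) {
  presets <- list(
    midfrontal     = c(0, 0.30),
    left_temporal  = c(-0.80, 0.05),
    right_temporal = c(0.80, 0.05),
    occipital      = c(0, -0.85),
    central        = c(0, 0)
  )
  if (is.character(center)) {
    if (!center %in% names(presets))
      stop("unknown topography preset: ", center, call. = FALSE)
    center <- presets[[center]]
  }
  stopifnot(is.numeric(center), length(center) == 2, sigma > 0)
  eeg <- layout[layout$type == "eeg", ]
  d2 <- (eeg$x - center[1])^2 + (eeg$y - center[2])^2
  w <- exp(-d2 / (2 * sigma^2))
  w <- w / sqrt(sum(w^2))
  stats::setNames(w, eeg$name)
}
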