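#!/usr/bin/env Rscript
# Stage 5 — static report per cohort: time-frequency t-maps with cluster
# outlines and the theta ROI box, plus the ROI and behavioral tables, and a
# topographical activation-pattern map for the congruency decoder.

source("analysis/00_config.R")

for (name in names(cohorts)) {
  run_dir <- file.path("results", name)
  rep_dir <- render_report(run_dir)

  # activation pattern of the congruency decoder inside the theta ROI
  pdir <- file.path(run_dir, "participants")
  pats <- NULL
  for (p in seq_len(N_PARTICIPANTS)) {
    fp <- file.path(pdir, sprintf("p%02d_auc_congruency.rds", p))
    if (!file.exists(fp)) next
    res <- readRDS(fp)
    ep <- read_epochs(file.path(pdir, sprintf("p%02d_clean", p)))
    keep <- jsonlite::read_json(file.path(pdir, sprintf("p%02d_kept.json", p)),
                                simplifyVector = TRUE)
    ep <- subset_epochs(ep, match(keep$decoding, ep$events$trial))
    tf <- compute_tf_power(ep, freqs = TF_FREQS)
    fsel <- tf$freqs >= 2 & tf$freqs <= 8
    tsel <- tf$times >= 0.1 & tf$times <= 0.7
    roi_data <- apply(tf$power[, , fsel, tsel, drop = FALSE], c(1, 2), mean)
    wsel <- which(res$freqs >= 2 & res$freqs <= 8)
    wt <- apply(res$weights[, wsel, , drop = FALSE], 1, mean, na.rm = TRUE)
    ap <- compute_activation_pattern(wt, roi_data)
    pats <- rbind(pats, ap$pattern / sqrt(sum(ap$pattern^2)))
  }
  topo <- colMeans(pats)
  lay <- read_epochs(file.path(pdir, "p01_clean"))$layout
  lay <- lay[lay$type == "eeg", ]
  png(file.path(rep_dir, "topo_congruency.png"), width = 480, height = 480)
  sc <- topo / max(abs(topo))
  plot(lay$x, lay$y, cex = 3.5, pch = 21,
       bg = grDevices::hcl.colors(101, "Blue-Red 3")[round(50 * sc) + 51],
       xlab = "", ylab = "", axes = FALSE, asp = 1,
       main = sprintf("congruency activation pattern (%s)", name))
  text(lay$x, lay$y - 0.12, lay$name, cex = 0.6)
  dev.off()
  cat(sprintf("cohort %-10s report written to %s (peak channel: %s)\n",
              name, rep_dir, lay$name[which.max(abs(topo))]))
}
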