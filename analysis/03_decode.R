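#!/usr/bin/env Rscript
# Stage 3 — single-trial wavelet power and per-bin 10-fold shrinkage-LDA
# decoding of congruency (and of content/location as control features on the
# cleaned, balanced trials). Writes one AUC map per participant and feature.

source("analysis/00_config.R")

features <- c("congruency", "content", "location")

for (name in names(cohorts)) {
  pdir <- file.path("results", name, "participants")
  for (p in seq_len(N_PARTICIPANTS)) {
    keep <- jsonlite::read_json(file.path(pdir, sprintf("p%02d_kept.json", p)),
                                simplifyVector = TRUE)
    if (isTRUE(keep$excluded)) next
    ep <- read_epochs(file.path(pdir, sprintf("p%02d_clean", p)))
    # keep$decoding holds original trial ids; map them into the cleaned set
    idx <- match(keep$decoding, ep$events$trial)
    ep <- subset_epochs(ep, idx)
    tf <- compute_tf_power(ep, freqs = TF_FREQS)
    tsel <- seq(1, length(tf$times), DECODE_TIME_STEP)
    for (ft in features) {
      labels <- switch(ft, congruency = ep$events$congruency,
                       content = ep$events$sound_content,
                       location = ep$events$sound_location)
      res <- decode_tf_map(tf, labels, feature = ft, n_folds = N_FOLDS,
                           seed = derive_seed(MASTER_SEED, "dec", name, p, ft),
                           time_sel = tsel)
      saveRDS(res, file.path(pdir, sprintf("p%02d_auc_%s.rds", p, ft)))
    }
    cat(sprintf("cohort %-10s p%02d decoded (%d trials kept)\n",
                name, p, nrow(ep$events)))
  }
}
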