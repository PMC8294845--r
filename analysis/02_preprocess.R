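#!/usr/bin/env Rscript
# Stage 2 — preprocessing: 0.01-50 Hz band-pass, earlobe re-reference,
# two-pass artifact rejection (VEOG 100 uV, EEG 300 uV in 0-800 ms),
# participant screening, trial selection and joint cell balancing.
# Writes cleaned epochs and per-participant kept-trial records.

source("analysis/00_config.R")

for (name in names(cohorts)) {
  pdir <- results_dir(name, "participants")
  cfg <- cohort_config(name)
  fracs <- numeric(N_PARTICIPANTS)
  kept <- vector("list", N_PARTICIPANTS)
  for (p in seq_len(N_PARTICIPANTS)) {
    ep <- read_epochs(file.path(pdir, sprintf("p%02d_epochs", p)))
    ep <- bandpass_filter(ep, 0.01, 50)
    ep <- rereference(ep)
    rej <- reject_artifacts(ep)
    fracs[p] <- rej$report$fraction_total
    write_epochs(rej$epochs, file.path(pdir, sprintf("p%02d_clean", p)))
    behav <- read.csv(file.path(pdir, sprintf("p%02d_behavior.csv", p)))
    surv <- which(rej$report$trials$keep)
    dec <- intersect(surv, select_trials(behav, cfg$task, "decoding"))
    cells <- interaction(behav$sound_content, behav$sound_location)[dec]
    bal <- dec[balance_classes(seq_along(dec), cells = cells,
                               seed = derive_seed(MASTER_SEED, "bal", name, p))]
    kept[[p]] <- list(
      decoding = bal,
      behavior = select_trials(behav, cfg$task, "behavior_stats"),
      rejected_fraction = fracs[p])
  }
  excl <- screen_participants(fracs)
  for (p in seq_len(N_PARTICIPANTS)) {
    kept[[p]]$excluded <- p %in% excl
    jsonlite::write_json(kept[[p]], file.path(pdir, sprintf("p%02d_kept.json", p)),
                         digits = NA, auto_unbox = TRUE)
  }
  cat(sprintf(
    "cohort %-10s rejected %.1f%% of epochs (SD %.1f%%); %d participant(s) excluded\n",
    name, 100 * mean(fracs), 100 * sd(fracs), length(excl)))
}
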