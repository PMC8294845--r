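# Shared configuration of the analysis chain.
#
# Two simulated cohorts contrast task relevance of the auditory features:
#   "relevant"   — auditory content discrimination; conflict (incongruent
#                  content/location) drives a midfrontal theta burst.
#   "irrelevant" — vertical random-dot-motion task; the same sounds play but
#                  no congruency-dependent neural effect is injected.
# The downstream scripts must flag the theta conflict signature only in the
# first cohort.

library(conflictMVPA)

MASTER_SEED <- 20260926
N_PARTICIPANTS <- 6
N_TRIALS <- 96
N_EEG <- 16
TF_FREQS <- seq(2, 14, by = 2)
DECODE_TIME_STEP <- 4 # decode every 4th 64 Hz grid point (16 Hz)
N_FOLDS <- 10
N_PERM <- 500

cohorts <- list(
  relevant = list(
    task = "content_discrimination_1",
    effects = list(effect_spec(band = c(4, 6), window = c(0.1, 0.7),
                               topography = "midfrontal",
                               amplitude = c(congruent = 0, incongruent = 25))),
    conflict_rt_ms = 40),
  irrelevant = list(
    task = "vertical_rdm",
    effects = list(effect_spec(amplitude = c(congruent = 0, incongruent = 0))),
    conflict_rt_ms = 0)
)

cohort_config <- function(name) {
  co <- cohorts[[name]]
  synthetic_config(
    n_participants = N_PARTICIPANTS, n_trials = N_TRIALS,
    task = co$task, n_eeg_channels = N_EEG,
    effects = co$effects,
    blink_prob = 0.05, hv_prob = 0.02,
    behavior = behavior_params(conflict_rt_ms = co$conflict_rt_ms),
    seed = derive_seed(MASTER_SEED, "cohort", name))
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
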