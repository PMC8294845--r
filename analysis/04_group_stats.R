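#!/usr/bin/env Rscript
# Stage 4 — group inference per cohort: one-sided t-maps against chance,
# cluster-based permutation correction, theta-ROI statistics with Cohen's dz
# and JZS Bayes factors, an ANCOVA of ROI accuracy on cohort x feature, and
# the behavioral conflict effects. Writes JSON/TSV tables consumed by the
# report stage.

source("analysis/00_config.R")

features <- c("congruency", "content", "location")
roi_rows <- list()

for (name in names(cohorts)) {
  pdir <- file.path("results", name, "participants")
  clus <- list()
  for (ft in features) {
    paths <- Filter(file.exists,
                    file.path(pdir, sprintf("p%02d_auc_%s.rds",
                                            seq_len(N_PARTICIPANTS), ft)))
    res_list <- lapply(paths, readRDS)
    freqs <- res_list[[1]]$freqs
    tsel <- which(!is.na(res_list[[1]]$auc[1, ]))
    times <- res_list[[1]]$times[tsel]
    maps <- array(NA_real_, c(length(res_list), length(freqs), length(tsel)))
    for (i in seq_along(res_list)) maps[i, , ] <- res_list[[i]]$auc[, tsel]
    cl <- cluster_permutation_test(maps, n_perm = N_PERM,
                                   seed = derive_seed(MASTER_SEED, "cl", name, ft))
    roi <- roi_summary(maps, freqs, times)
    clus[[ft]] <- list(cluster = cl, freqs = freqs, times = times, roi = roi)
    roi_rows[[paste(name, ft)]] <- data.frame(
      cohort = name, feature = ft, n = roi$n, mean_auc = roi$mean_auc,
      t = roi$t, df = roi$df, p = roi$p, dz = roi$dz, bf01 = roi$bf01,
      n_sig_clusters = sum(vapply(cl$clusters, function(x) x$p <= 0.05,
                                  logical(1))))
    cat(sprintf(
      "%-10s %-10s ROI AUC %.3f  t(%d)=%+.2f p=%.3f dz=%+.2f BF01=%.2f  sig clusters: %d\n",
      name, ft, roi$mean_auc, roi$df, roi$t, roi$p, roi$dz, roi$bf01,
      roi_rows[[paste(name, ft)]]$n_sig_clusters))
  }
  saveRDS(clus, file.path("results", name, "cluster_stats.rds"))
  roi_cohort <- do.call(rbind, roi_rows[grep(paste0("^", name), names(roi_rows))])
  jsonlite::write_json(roi_cohort, file.path("results", name, "roi_stats.json"),
                       digits = NA, auto_unbox = TRUE)

  # behavioral conflict effects on the behavior-selected trials
  tabs <- lapply(seq_len(N_PARTICIPANTS), function(p) {
    b <- read.csv(file.path(pdir, sprintf("p%02d_behavior.csv", p)))
    keep <- jsonlite::read_json(file.path(pdir, sprintf("p%02d_kept.json", p)),
                                simplifyVector = TRUE)
    b[keep$behavior, ]
  })
  bc <- behavior_conflict_effects(tabs)
  jsonlite::write_json(bc$tests, file.path("results", name, "behavior_stats.json"),
                       digits = NA, auto_unbox = TRUE)
  cat(sprintf("%-10s behavioral conflict effect: %+.0f ms (t=%+.2f, p=%.3g)\n",
              name, bc$tests["rt_ms", "mean_diff"], bc$tests["rt_ms", "t"],
              bc$tests["rt_ms", "p"]))
}

roi_tab <- do.call(rbind, roi_rows)
write.table(roi_tab, file.path(results_dir(), "roi_table.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# does ROI accuracy depend on cohort (task relevance) and decoded feature?
anc_in <- data.frame(auc = unlist(lapply(names(cohorts), function(name) {
  lapply(features, function(ft) {
    clus <- readRDS(file.path("results", name, "cluster_stats.rds"))
    clus[[ft]]$roi$roi_auc
  })
})))
anc_in$task <- rep(names(cohorts), each = N_PARTICIPANTS * length(features))
anc_in$feature <- rep(rep(features, each = N_PARTICIPANTS), times = length(cohorts))
anc <- ancova_task_feature(anc_in)
write.table(anc, file.path(results_dir(), "ancova_task_feature.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nANCOVA of ROI AUC on task x feature:\n")
print(anc, digits = 3)
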