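#' Per-bin one-sample t-map of group AUC
#'
#' One-sample t statistic against chance (0.5) at every (frequency, time)
#' bin, across participants. Bins with zero variance across participants get
#' t = 0 (never significant) rather than +/- infinity.
#'
#' @param auc_maps numeric array participants x frequencies x times (a
#'   matrix participants x bins is also accepted).
#' @param mu chance level tested against.
#' @return array of t statistics with the map's dimensions.
#' @export
group_tmap <- function(auc_maps, mu = 0.5) {
  d <- dim(auc_maps)
  is_3d <- length(d) == 3
  a <- if (is_3d) matrix(auc_maps, nrow = d[1]) else as.matrix(auc_maps)
  n <- nrow(a)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  m <- colMeans(a) - mu
  s <- apply(a, 2, sd)
  t <- ifelse(s == 0, 0, m / (s / sqrt(n)))
  if (is_3d) array(t, dim = d[2:3]) else t
}

#' Label connected components of a binary grid
#'
#' Finds maximal connected components of `TRUE` cells in a 2-D logical
#' matrix under 4-connectivity (2-neighbour connectivity when the matrix has
#' a single row, the time-only variant).
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape: 0 outside clusters, cluster ids
#'   1..k inside.
#' @export
label_clusters <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      r <- (cell - 1L) %% nr + 1L
      c <- (cell - 1L) %/% nr + 1L
      nb <- c(if (r > 1) cell - 1L, if (r < nr) cell + 1L,
              if (c > 1) cell - nr, if (c < nc) cell + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Cluster-based permutation test on group AUC maps
#'
#' Corrects per-bin one-sided t-tests against chance for multiple comparisons
#' over time and frequency. The observed t-map is thresholded at the
#' cluster-forming level (per-bin one-sided p < `cluster_alpha`), maximal
#' 4-connected components are formed and scored by their mass (sum of member
#' t values). The null distribution of the maximal cluster mass is built by
#' randomly sign-flipping each participant's deviation map (AUC - 0.5) —
#' the one-sample exchangeability argument — and the corrected p of each
#' observed cluster is `(1 + #{null >= mass}) / (1 + n_perm)`.
#'
#' @param auc_maps array participants x frequencies x times.
#' @param alpha significance level for the corrected cluster p values.
#' @param cluster_alpha cluster-forming per-bin level.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed permutation seed.
#' @param mu chance level.
#' @return a `cluster_result`: `clusters` (list of `bins` index matrix,
#'   `mass`, `p`), `mask` (logical map of bins in significant clusters),
#'   `tmap`, `t_crit`, `n_perm`, `seed`.
#' @export
cluster_permutation_test <- function(auc_maps, alpha = 0.05,
                                     cluster_alpha = 0.05, n_perm = 1000,
                                     seed = 1, mu = 0.5) {
  d <- dim(auc_maps)
  stopifnot(length(d) == 3)
  n <- d[1]
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  t_crit <- qt(1 - cluster_alpha, df = n - 1)
  dev <- matrix(auc_maps, nrow = n) - mu # participants x bins
  ssq <- colSums(dev^2) # invariant under sign flips

  tmap_vec <- function(m) { # column means -> t, given fixed ssq
    v <- (ssq - n * m^2) / (n - 1)
    ifelse(v <= 0, 0, m / sqrt(v / n))
  }
  max_mass <- function(tv) {
    msk <- matrix(tv > t_crit, d[2], d[3])
    if (!any(msk)) return(0)
    lab <- label_clusters(msk)
    tm <- matrix(tv, d[2], d[3])
    max(tapply(tm[lab > 0], lab[lab > 0], sum))
  }

  t_obs <- tmap_vec(colMeans(dev))
  obs_mask <- matrix(t_obs > t_crit, d[2], d[3])
  lab <- label_clusters(obs_mask)
  t_mat <- matrix(t_obs, d[2], d[3])
  k <- max(lab)
  masses <- if (k > 0) as.numeric(tapply(t_mat[lab > 0], lab[lab > 0], sum)) else numeric(0)

  set.seed(seed)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    null_max[b] <- max_mass(tmap_vec(colMeans(s * dev)))
  }

  clusters <- lapply(seq_len(k), function(ci) {
    list(bins = which(lab == ci, arr.ind = TRUE),
         mass = masses[ci],
         p = (1 + sum(null_max >= masses[ci])) / (1 + n_perm))
  })
  sig <- vapply(clusters, function(cl) cl$p <= alpha, logical(1))
  mask <- matrix(FALSE, d[2], d[3])
  for (ci in which(sig)) mask[clusters[[ci]]$bins] <- TRUE
  structure(list(clusters = clusters, mask = mask, tmap = t_mat,
                 t_crit = t_crit, n_perm = n_perm, seed = seed,
                 alpha = alpha, cluster_alpha = cluster_alpha),
            class = "cluster_result")
}

#' ROI summary of decoding maps
#'
#' Averages each participant's AUC over the bins whose centers fall inside
#' the closed region of interest (default the predefined theta ROI, 2-8 Hz by
#' 100-700 ms), then tests the group against chance with a one-sided t-test
#' and reports Cohen's dz (= t / sqrt(n)) and the JZS Bayes factor in favor
#' of the null.
#'
#' @param auc_maps array participants x frequencies x times (bins outside the
#'   decoded selection may be NA; they are ignored).
#' @param freqs,times bin-center axes of the maps.
#' @param roi `list(freq = c(lo, hi), time = c(lo, hi))`, closed intervals.
#' @param mu chance level.
#' @param alternative `"greater"` (decoding above chance) or `"two.sided"`.
#' @param r Cauchy prior scale for the Bayes factor.
#' @return a `roi_stats` list: `roi_auc` per participant, `mean_auc`, `t`,
#'   `df`, `p`, `dz`, `bf01`, `roi`.
#' @export
roi_summary <- function(auc_maps, freqs, times,
                        roi = list(freq = c(2, 8), time = c(0.1, 0.7)),
                        mu = 0.5, alternative = "greater", r = 0.71) {
  d <- dim(auc_maps)
  stopifnot(length(d) == 3, d[2] == length(freqs), d[3] == length(times))
  fsel <- freqs >= roi$freq[1] & freqs <= roi$freq[2]
  tsel <- times >= roi$time[1] - 1e-9 & times <= roi$time[2] + 1e-9
  if (!any(fsel) || !any(tsel)) stop("empty ROI", call. = FALSE)
  roi_auc <- apply(auc_maps[, fsel, tsel, drop = FALSE], 1, mean, na.rm = TRUE)
  n <- length(roi_auc)
  s <- sd(roi_auc)
  one_sided <- alternative == "greater"
  if (s > 0) {
    t_val <- (mean(roi_auc) - mu) / (s / sqrt(n))
    p <- if (one_sided) pt(t_val, n - 1, lower.tail = FALSE) else
      2 * pt(abs(t_val), n - 1, lower.tail = FALSE)
    bf01 <- bayes_factor_one_sample(t_val, n,
                                    sided = if (one_sided) "greater" else "two",
                                    r = r)
  } else { # degenerate: identical ROI means across participants
    t_val <- sign(mean(roi_auc) - mu) * Inf
    if (is.nan(t_val) || t_val == 0) t_val <- 0
    p <- if (t_val > 0) 0 else 1
    bf01 <- if (t_val == 0) NA_real_ else if (t_val > 0) 0 else Inf
  }
  structure(list(roi_auc = roi_auc, mean_auc = mean(roi_auc), t = t_val,
                 df = n - 1, p = p, dz = t_val / sqrt(n),
                 bf01 = bf01, roi = roi, mu = mu, n = n),
            class = "roi_stats")
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor in favor of the null
#' (BF01) for a one-sample (or paired) t statistic, with a Cauchy prior of
#' scale `r` on the standardized effect size. The marginal likelihood under
#' the alternative is obtained by numerical integration of the noncentral-t
#' likelihood over the prior; one-sided variants truncate (and renormalize)
#' the prior to the stated direction.
#'
#' @param t observed t statistic.
#' @param n sample size (degrees of freedom `n - 1`).
#' @param sided `"two"`, `"greater"` or `"less"`.
#' @param r Cauchy prior scale (default 0.71, the scale used for the
#'   decoding-versus-chance tests; 1/sqrt(2) is the common software default).
#' @return BF01 (> 0); values above 1 favor the null.
#' @export
#' @examples
#' bayes_factor_one_sample(-0.50, 24, sided = "greater", r = 0.71)  # ~6.5
bayes_factor_one_sample <- function(t, n, sided = c("two", "greater", "less"),
                                    r = 0.71) {
  sided <- match.arg(sided)
  if (!is.finite(t)) stop("t must be finite", call. = FALSE)
  stopifnot(n >= 2, r > 0)
  nu <- n - 1
  # dt() with an ncp flags its (ample) precision limit; silence the notes
  lik <- function(delta) suppressWarnings(dt(t, nu, ncp = sqrt(n) * delta))
  marg <- switch(sided,
    two = integrate(function(d) lik(d) * dcauchy(d, 0, r),
                    -Inf, Inf, rel.tol = 1e-9)$value,
    greater = integrate(function(d) lik(d) * 2 * dcauchy(d, 0, r),
                        0, Inf, rel.tol = 1e-9)$value,
    less = integrate(function(d) lik(d) * 2 * dcauchy(d, 0, r),
                     -Inf, 0, rel.tol = 1e-9)$value)
  bf10 <- marg / dt(t, nu)
  1 / bf10
}

#' Signal-detection sensitivity (d-prime)
#'
#' d' = z(hit rate) - z(false-alarm rate), computed from raw counts with the
#' log-linear correction (0.5 added to every cell, 1 to every denominator)
#' applied by default so extreme rates stay finite.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative counts.
#' @param correction apply the log-linear correction (default TRUE).
#' @return list with `hit_rate`, `fa_rate`, `dprime`.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections,
                   correction = TRUE) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (hits + misses < 1 || false_alarms + correct_rejections < 1)
    stop("need at least one signal and one noise trial", call. = FALSE)
  if (correction) {
    h <- (hits + 0.5) / (hits + misses + 1)
    fa <- (false_alarms + 0.5) / (false_alarms + correct_rejections + 1)
  } else {
    h <- hits / (hits + misses)
    fa <- false_alarms / (false_alarms + correct_rejections)
  }
  list(hit_rate = h, fa_rate = fa, dprime = qnorm(h) - qnorm(fa))
}

#' Behavioral conflict effects across participants
#'
#' For each participant, computes the incongruent-minus-congruent difference
#' in mean correct RT and in error rate, then tests the group differences
#' with paired (one-sample on differences) t-tests, reporting t, p, Cohen's
#' dz and a Bayes-factor follow-up.
#'
#' @param tables list of per-participant `BehavioralTable`s (already
#'   trial-selected with [select_trials()]).
#' @param alternative sidedness of the t-tests.
#' @param r Cauchy prior scale of the Bayesian follow-up.
#' @return a list with per-participant `delta_rt_ms` and `delta_er`, and a
#'   data.frame `tests` (one row per measure: mean difference, t, df, p, dz,
#'   bf01).
#' @export
behavior_conflict_effects <- function(tables, alternative = "two.sided",
                                      r = 0.707) {
  stopifnot(is.list(tables))
  if (length(tables) < 2)
    stop("need at least 2 participants for a paired test", call. = FALSE)
  one <- function(tb) {
    for (lev in c("congruent", "incongruent"))
      if (!any(tb$congruency == lev))
        stop("both congruency levels must be present per participant",
             call. = FALSE)
    con <- tb$congruency == "congruent"
    rt_c <- mean(tb$rt_ms[con & tb$correct], na.rm = TRUE)
    rt_i <- mean(tb$rt_ms[!con & tb$correct], na.rm = TRUE)
    er_c <- mean(!tb$correct[con])
    er_i <- mean(!tb$correct[!con])
    c(delta_rt = rt_i - rt_c, delta_er = er_i - er_c)
  }
  deltas <- t(vapply(tables, one, numeric(2)))
  n <- nrow(deltas)
  test_one <- function(x) {
    tt <- t.test(x, alternative = alternative)
    t_val <- unname(tt$statistic)
    sided <- switch(alternative, two.sided = "two", greater = "greater",
                    less = "less")
    data.frame(mean_diff = mean(x), t = t_val, df = n - 1,
               p = unname(tt$p.value), dz = t_val / sqrt(n),
               bf01 = bayes_factor_one_sample(t_val, n, sided = sided, r = r))
  }
  tests <- rbind(rt_ms = test_one(deltas[, "delta_rt"]),
                 error_rate = test_one(deltas[, "delta_er"]))
  tests$measure <- rownames(tests)
  list(delta_rt_ms = deltas[, "delta_rt"], delta_er = deltas[, "delta_er"],
       tests = tests)
}
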