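# orthonormal contrast basis for one factor with k levels: (k-1) x k matrix
# with orthonormal rows, each orthogonal to the unit vector
.orth_contrasts <- function(k) {
  q <- qr.Q(qr(cbind(rep(1, k), stats::contr.poly(k))))
  t(q[, -1, drop = FALSE])
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical fully-within-subject ANOVA for one to three crossed factors.
#' Replicated observations are first averaged to participant-by-cell means.
#' Each effect is evaluated through its orthonormal contrast scores: the
#' effect sum of squares is `n * sum(mean(z)^2)` over the effect's contrast
#' dimensions, the error term is the participant-by-effect interaction, and
#' partial eta squared is `SS_effect / (SS_effect + SS_error)`. For effects
#' with more than one degree of freedom, sphericity is checked with
#' Mauchly's test and, when rejected (p < `mauchly_alpha`), degrees of
#' freedom are Greenhouse-Geisser corrected with the epsilon estimated from
#' the covariance of the contrast scores.
#'
#' @param data long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor column names
#'   (1 to 3).
#' @param subject name of the subject identifier column.
#' @param mauchly_alpha level of the Mauchly sphericity gate.
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `pes` (partial eta squared), `epsilon`, `sphericity_p`,
#'   `gg_applied` (corrected df are reported in `df1`/`df2` when applied).
#' @export
rm_anova <- function(data, dv, within, subject = "participant",
                     mauchly_alpha = 0.05) {
  stopifnot(length(within) >= 1, length(within) <= 3,
            all(c(dv, within, subject) %in% names(data)))
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])
  cells <- interaction(data[within], drop = FALSE, lex.order = TRUE)
  agg <- aggregate(data[[dv]], by = list(subject = data[[subject]], cell = cells),
                   FUN = mean)
  subj_lev <- levels(data[[subject]])
  wide <- matrix(NA_real_, length(subj_lev), nlevels(cells),
                 dimnames = list(subj_lev, levels(cells))) # subjects x cells
  wide[cbind(match(agg$subject, subj_lev), match(agg$cell, levels(cells)))] <- agg$x
  if (any(is.na(wide))) stop("missing cells in the within design", call. = FALSE)
  n <- nrow(wide)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)

  ks <- vapply(within, function(w) nlevels(data[[w]]), integer(1))
  # cells vary with lex.order = TRUE: first factor slowest
  rows <- list()
  subsets <- unlist(lapply(seq_along(within), function(m)
    utils::combn(seq_along(within), m, simplify = FALSE)), recursive = FALSE)
  for (ss in subsets) {
    basis <- 1
    for (j in seq_along(within)) {
      mj <- if (j %in% ss) .orth_contrasts(ks[j]) else
        matrix(1 / sqrt(ks[j]), 1, ks[j])
      basis <- kronecker(basis, mj)
    }
    z <- wide %*% t(basis) # subjects x q contrast scores
    # scale: averaging over excluded factors used weight 1/sqrt(k) per level,
    # i.e. sqrt(k) times the plain mean -> SS formulas absorb it exactly
    q <- nrow(basis)
    zbar <- colMeans(z)
    ss_eff <- n * sum(zbar^2)
    zc <- sweep(z, 2, zbar)
    ss_err <- sum(zc^2)
    df1 <- q
    df2 <- q * (n - 1)
    f <- if (ss_eff <= .Machine$double.eps * max(1, ss_err)) 0 else
      (ss_eff / df1) / (ss_err / df2)
    eps <- 1; sph_p <- NA_real_; gg <- FALSE
    if (q > 1) {
      sig <- crossprod(zc) / (n - 1)
      ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
      eps <- sum(ev)^2 / (q * sum(ev^2))
      # Mauchly's W with chi-square approximation
      if (all(ev > 1e-12) && n - 1 > q) {
        w_stat <- prod(ev) / (mean(ev)^q)
        rho <- 1 - (2 * q^2 + q + 2) / (6 * q * (n - 1))
        chi <- -(n - 1) * rho * log(w_stat)
        sph_p <- pchisq(chi, q * (q + 1) / 2 - 1, lower.tail = FALSE)
        gg <- is.finite(sph_p) && sph_p < mauchly_alpha
      }
    }
    use_eps <- if (gg) eps else 1
    p <- if (f == 0 && ss_err == 0) NA_real_ else
      pf(f, df1 * use_eps, df2 * use_eps, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      effect = paste(within[ss], collapse = ":"),
      df1 = df1 * use_eps, df2 = df2 * use_eps, F = f, p = p,
      pes = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
      epsilon = eps, sphericity_p = sph_p, gg_applied = gg,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Type-III ANCOVA of ROI decoding accuracy on task and feature
#'
#' Linear model `auc ~ task * feature` with sum-to-zero contrasts and
#' Type-III F tests (each term tested by the increase in residual sum of
#' squares when its columns are removed from the full model), with partial
#' eta squared per effect.
#'
#' @param roi_aucs data.frame with columns `auc`, `task`, `feature` (one row
#'   per participant x task x feature observation).
#' @return data.frame with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p`, `pes`.
#' @export
ancova_task_feature <- function(roi_aucs) {
  stopifnot(all(c("auc", "task", "feature") %in% names(roi_aucs)))
  df <- roi_aucs
  df$task <- factor(df$task)
  df$feature <- factor(df$feature)
  if (any(table(df$task, df$feature) == 0))
    stop("every task x feature cell needs observations", call. = FALSE)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  full <- lm(auc ~ task * feature, data = df)
  X <- model.matrix(full)
  asg <- attr(X, "assign")
  terms_lab <- attr(terms(full), "term.labels")
  rss_full <- sum(residuals(full)^2)
  df_res <- df.residual(full)
  tol <- 1e-10 * max(1, sum(df$auc^2)) # an exactly-fit response has rss ~ 0
  rows <- lapply(seq_along(terms_lab), function(ti) {
    keep <- asg != ti
    red <- lm.fit(X[, keep, drop = FALSE], df$auc)
    ss_t <- sum(red$residuals^2) - rss_full
    df_t <- sum(asg == ti)
    f <- (ss_t / df_t) / (rss_full / df_res)
    if (rss_full <= tol) f <- if (ss_t <= tol) 0 else Inf
    data.frame(effect = terms_lab[ti], df1 = df_t, df2 = df_res,
               F = max(f, 0),
               p = pf(max(f, 0), df_t, df_res, lower.tail = FALSE),
               pes = if (ss_t + rss_full > 0) ss_t / (ss_t + rss_full) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
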