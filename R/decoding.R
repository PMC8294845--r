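#' Rank-based AUC of continuous decision values
#'
#' Area under the ROC curve by the all-pairs (Mann-Whitney) definition:
#' the fraction of (positive, negative) pairs in which the positive trial
#' received the larger decision value, ties counting one half. Equals the
#' Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param decision numeric decision values.
#' @param labels logical or two-level factor; `TRUE` (or the second level) is
#'   the positive class.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc_rank(c(0.9, 0.8, 0.3), c(TRUE, TRUE, FALSE))  # 1
auc_rank <- function(decision, labels) {
  pos <- .as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(decision) # average ranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly two classes", call. = FALSE)
  f == levels(f)[2]
}

# internal: Ledoit-Wolf shrinkage of a pooled within-class covariance toward
# a scaled identity. `xc` is the class-centered training matrix (n x p).
.lw_covariance <- function(xc, n_classes = 2) {
  n <- nrow(xc); p <- ncol(xc)
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  # phi = average squared deviation of per-trial outer products from S
  phi <- sum(crossprod(xc^2)) / n^2 - sum(s^2) / n
  delta2 <- sum((s - diag(mu, p))^2)
  lambda <- if (delta2 > 0) max(0, min(1, phi / delta2)) else 1
  sig <- (1 - lambda) * s + diag(lambda * mu, p)
  # unbiased-style rescale for the class means removed
  sig <- sig * n / max(n - n_classes, 1)
  list(sigma = sig, lambda = lambda)
}

# internal: train a two-class shrinkage LDA; returns weights and offset such
# that decision = X %*% w + b is the signed distance side of the hyperplane
.fit_lda <- function(x, pos) {
  mu1 <- colMeans(x[pos, , drop = FALSE])
  mu0 <- colMeans(x[!pos, , drop = FALSE])
  xc <- x
  xc[pos, ] <- sweep(x[pos, , drop = FALSE], 2, mu1)
  xc[!pos, ] <- sweep(x[!pos, , drop = FALSE], 2, mu0)
  cv <- .lw_covariance(xc)
  w <- solve(cv$sigma, mu1 - mu0)
  b <- -sum(w * (mu1 + mu0)) / 2
  list(w = w, b = b, lambda = cv$lambda)
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each trial to one of `n_folds` folds, stratified by class (and
#' optionally by a finer cell factor) so every fold contains near-equal
#' class counts; deterministic given the seed.
#'
#' @param labels class labels.
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @param cells optional stratification cells (e.g. content x location).
#' @return integer fold index per trial.
#' @export
assign_folds <- function(labels, n_folds = 20, seed = 1, cells = NULL) {
  strata <- if (is.null(cells)) as.character(labels) else as.character(cells)
  set.seed(seed)
  folds <- integer(length(labels))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

#' Cross-validated shrinkage-LDA decoding of one feature matrix
#'
#' Trains a regularized (Ledoit-Wolf shrinkage) linear discriminant on each
#' training split of a stratified n-fold scheme, collects continuous decision
#' values for the held-out trials, pools them across folds and scores a
#' single rank-based AUC. Weights are averaged over folds.
#'
#' @param features numeric matrix, trials x features (finite).
#' @param labels two-class labels, each class with at least `n_folds` trials.
#' @param n_folds number of cross-validation folds.
#' @param seed fold-assignment seed (ignored when `folds` is given).
#' @param folds optional precomputed fold assignment from [assign_folds()].
#' @return `list(auc, weights, lambda)` where `lambda` is the mean shrinkage
#'   intensity across folds.
#' @export
crossval_decode <- function(features, labels, n_folds = 20, seed = 1,
                            folds = NULL) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("features must be finite", call. = FALSE)
  pos <- .as_positive(labels)
  if (min(sum(pos), sum(!pos)) < n_folds)
    stop("each class needs at least n_folds trials", call. = FALSE)
  if (is.null(folds)) folds <- assign_folds(pos, n_folds, seed)
  dv <- numeric(nrow(features))
  w_acc <- numeric(ncol(features))
  lam <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    te <- folds == k
    fit <- .fit_lda(features[!te, , drop = FALSE], pos[!te])
    dv[te] <- features[te, , drop = FALSE] %*% fit$w + fit$b
    w_acc <- w_acc + fit$w
    lam[k] <- fit$lambda
  }
  list(auc = auc_rank(dv, pos), weights = w_acc / n_folds,
       lambda = mean(lam))
}

#' Time-frequency decoding map for one participant
#'
#' Applies [crossval_decode()] independently at every (frequency, time) bin
#' of a [compute_tf_power()] result, using the per-channel power vector as
#' features and re-using one fold assignment across all bins.
#'
#' @param tf a `tf_power` object.
#' @param labels two-class labels, one per trial (balanced beforehand with
#'   [balance_classes()]).
#' @param feature name of the decoded feature (metadata).
#' @param n_folds,seed cross-validation controls.
#' @param freq_sel,time_sel optional logical/index selections restricting the
#'   decoded bins (e.g. an ROI or a decimated time grid); unselected bins are
#'   `NA` in the output.
#' @return a `decoding_result`: `auc` (freq x time), `weights`
#'   (channels x freq x time), `freqs`, `times`, `feature`, `domain = "tf"`,
#'   CV metadata.
#' @export
decode_tf_map <- function(tf, labels, feature = "congruency", n_folds = 20,
                          seed = 1, freq_sel = NULL, time_sel = NULL) {
  stopifnot(inherits(tf, "tf_power"))
  d <- dim(tf$power)
  if (length(labels) != d[1]) stop("one label per trial required", call. = FALSE)
  pos <- .as_positive(labels)
  folds <- assign_folds(pos, n_folds, seed)
  fi_set <- if (is.null(freq_sel)) seq_along(tf$freqs) else seq_along(tf$freqs)[freq_sel]
  ti_set <- if (is.null(time_sel)) seq_along(tf$times) else seq_along(tf$times)[time_sel]
  auc <- matrix(NA_real_, d[3], d[4], dimnames = list(tf$freqs, NULL))
  wts <- array(NA_real_, dim = c(d[2], d[3], d[4]))
  lam <- numeric(0)
  for (fi in fi_set) {
    for (ti in ti_set) {
      res <- crossval_decode(tf$power[, , fi, ti], pos, n_folds, folds = folds)
      auc[fi, ti] <- res$auc
      wts[, fi, ti] <- res$weights
      lam <- c(lam, res$lambda)
    }
  }
  structure(list(auc = auc, weights = wts, freqs = tf$freqs, times = tf$times,
                 channels = tf$channels, feature = feature, domain = "tf",
                 n_folds = n_folds, seed = seed,
                 auc_pooling = "decision values pooled across folds",
                 mean_shrinkage = mean(lam)),
            class = "decoding_result")
}

#' Time-domain decoding time course for one participant
#'
#' Decodes channel voltages per time point on the decoding grid (default
#' 64 Hz over -100 to 1000 ms; epochs are resampled by taking the nearest
#' sample of each grid point).
#'
#' @param epochs an `eeg_epochs` object.
#' @param labels two-class labels per trial.
#' @param feature decoded feature name (metadata).
#' @param n_folds,seed cross-validation controls.
#' @param crop,out_rate decoding grid definition.
#' @return a `decoding_result` with `domain = "time"`; `auc` is a
#'   1 x times matrix.
#' @export
decode_timecourse <- function(epochs, labels, feature = "content",
                              n_folds = 20, seed = 1, crop = c(-0.1, 1.0),
                              out_rate = 64) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  pos <- .as_positive(labels)
  folds <- assign_folds(pos, n_folds, seed)
  k_lo <- ceiling(crop[1] * out_rate - 1e-9)
  k_hi <- floor(crop[2] * out_rate + 1e-9)
  t_out <- (k_lo:k_hi) / out_rate
  centers <- round((t_out - epochs$times[1]) * epochs$srate) + 1
  if (any(centers < 1) || any(centers > length(epochs$times)))
    stop("decoding grid outside epoch", call. = FALSE)
  eeg <- channel_idx(epochs, "eeg")
  auc <- matrix(NA_real_, 1, length(t_out))
  wts <- array(NA_real_, dim = c(length(eeg), 1, length(t_out)))
  for (ti in seq_along(t_out)) {
    res <- crossval_decode(epochs$voltages[, eeg, centers[ti]], pos, n_folds,
                           folds = folds)
    auc[1, ti] <- res$auc
    wts[, 1, ti] <- res$weights
  }
  structure(list(auc = auc, weights = wts, freqs = NA, times = t_out,
                 channels = epochs$layout$name[eeg], feature = feature,
                 domain = "time", n_folds = n_folds, seed = seed,
                 auc_pooling = "decision values pooled across folds"),
            class = "decoding_result")
}

#' Transform classifier weights to an activation pattern
#'
#' Classifier weights are not interpretable as neural sources; the
#' corresponding activation pattern is obtained by multiplying the (bin- or
#' ROI-averaged) weight vector with the channel covariance of the feature
#' data the classifier saw.
#'
#' @param weights channel weight vector (ROI-averaged).
#' @param data trials x channels feature matrix (e.g. ROI-averaged power).
#' @return a list with `pattern` (channels), `sigma` (the covariance used).
#' @export
compute_activation_pattern <- function(weights, data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 trials to form a covariance",
                           call. = FALSE)
  if (length(weights) != ncol(data))
    stop("weights length must match channel count", call. = FALSE)
  sigma <- stats::cov(data)
  list(pattern = as.numeric(sigma %*% weights), sigma = sigma)
}
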