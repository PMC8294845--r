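test_that("rank AUC equals the all-pairs concordance oracle", {
  # closed-form worked example: 2/2 concordant pairs
  expect_equal(auc_rank(c(0.9, 0.8, 0.3), c(TRUE, TRUE, FALSE)), 1.0)

  allpairs <- function(dv, pos) {
    s <- 0; np <- which(pos); nn <- which(!pos)
    for (i in np) for (j in nn)
      s <- s + (dv[i] > dv[j]) + 0.5 * (dv[i] == dv[j])
    s / (length(np) * length(nn))
  }
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    dv <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # forces ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    expect_equal(auc_rank(dv, pos), allpairs(dv, pos))
    # Mann-Whitney U equivalence via an independent routine
    u <- suppressWarnings(wilcox.test(dv[pos], dv[!pos]))$statistic
    expect_equal(auc_rank(dv, pos), unname(u) / (sum(pos) * sum(!pos)))
  }
})

test_that("label flips map AUC to its complement", {
  set.seed(11)
  dv <- rnorm(40)
  pos <- runif(40) < 0.5
  expect_equal(auc_rank(dv, pos), 1 - auc_rank(dv, !pos))
})

test_that("cross-validated LDA separates separable data and not noise", {
  set.seed(12)
  n <- 200
  x <- matrix(rnorm(n * 8), n)
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  x[pos, 1] <- x[pos, 1] + 10 # huge margin
  expect_equal(crossval_decode(x, pos, n_folds = 20, seed = 1)$auc, 1.0)

  set.seed(13)
  x2 <- matrix(rnorm(400 * 8), 400)
  pos2 <- sample(rep(c(TRUE, FALSE), 200))
  auc <- crossval_decode(x2, pos2, n_folds = 20, seed = 1)$auc
  expect_equal(auc, 0.5, tolerance = 0.05 / 0.5)

  expect_error(crossval_decode(x[1:25, ], pos[1:25], n_folds = 20),
               "n_folds trials")
  xc <- x; xc[, 3] <- 1 # constant feature: shrinkage keeps weights finite
  expect_true(all(is.finite(crossval_decode(xc, pos, 10, 1)$weights)))
})

test_that("AUC is stable between 10 and 20 folds", {
  diffs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(400 * 8), 400)
    pos <- rep(c(TRUE, FALSE), 200)
    x[pos, 1:2] <- x[pos, 1:2] + 0.25
    a10 <- crossval_decode(x, pos, n_folds = 10, seed = s)$auc
    a20 <- crossval_decode(x, pos, n_folds = 20, seed = s)$auc
    abs(a10 - a20)
  }, numeric(1))
  expect_lt(max(diffs), 0.03)
})

test_that("tf-map decoding localizes an injected effect and is deterministic", {
  cfg <- synthetic_config(
    n_trials = 160, n_eeg_channels = 16,
    effects = list(effect_spec(band = c(5, 5), window = c(0.2, 0.6),
                               amplitude = c(congruent = 0, incongruent = 30))),
    blink_prob = 0, hv_prob = 0, seed = 3)
  sim <- simulate_participant(cfg, 1)
  tf <- compute_tf_power(sim$epochs, freqs = seq(2, 20, 2),
                         crop = c(0, 0.8))
  lab <- sim$epochs$events$congruency
  res <- decode_tf_map(tf, lab, n_folds = 10, seed = 4)
  peak <- which(res$auc == max(res$auc), arr.ind = TRUE)[1, ]
  expect_true(tf$freqs[peak[1]] %in% c(2, 4, 6))
  expect_true(tf$times[peak[2]] >= 0.1 && tf$times[peak[2]] <= 0.7)

  res2 <- decode_tf_map(tf, lab, n_folds = 10, seed = 4)
  expect_identical(res$auc, res2$auc)
})

test_that("time-domain decoding finds phase-locked effects in their window", {
  cfg <- synthetic_config(
    n_trials = 160, n_eeg_channels = 16,
    effects = list(effect_spec(band = c(5, 5), window = c(0.2, 0.4),
                               amplitude = c(congruent = -20, incongruent = 20),
                               phase_locked = TRUE)),
    blink_prob = 0, hv_prob = 0, seed = 5)
  sim <- simulate_participant(cfg, 1)
  res <- decode_timecourse(sim$epochs, sim$epochs$events$congruency,
                           n_folds = 10, seed = 6)
  inside <- res$times >= 0.2 & res$times <= 0.4
  outside <- res$times < 0.1 | res$times > 0.55
  # the evoked oscillation crosses zero inside its window, so pointwise AUC
  # dips periodically: the peak must be high, the outside mean at chance
  expect_gt(max(res$auc[1, inside]), 0.9)
  expect_gt(mean(res$auc[1, inside]), 0.6)
  expect_lt(mean(res$auc[1, outside]), 0.6)
})

test_that("activation patterns recover topographies and scale with the data", {
  # identity covariance: pattern proportional to weights
  set.seed(14)
  w <- rnorm(6)
  x <- matrix(rnorm(5000 * 6), 5000)
  ap <- compute_activation_pattern(w, x)
  expect_equal(ap$pattern / w, rep(mean(ap$pattern / w), 6), tolerance = 0.2)

  # scaling the data by c scales the pattern by c^2
  ap2 <- compute_activation_pattern(w, 3 * x)
  expect_equal(ap2$pattern, 9 * ap$pattern)

  # single-source recovery: data = topo * source + small noise
  set.seed(15)
  g <- gaussian_topography(eeg_layout_64(), "midfrontal")
  src <- rnorm(400, sd = 4)
  data <- outer(src, g) + matrix(rnorm(400 * 64), 400)
  pos <- src > 0
  fit <- crossval_decode(data, pos, n_folds = 10, seed = 2)
  ap3 <- compute_activation_pattern(fit$weights, data)
  expect_gt(cor(ap3$pattern, g), 0.9)

  expect_error(compute_activation_pattern(w, x[1, , drop = FALSE]), "2 trials")
  expect_error(compute_activation_pattern(w[1:3], x), "length")
})

test_that("stratified folds are balanced and reproducible", {
  lab <- rep(c("a", "b"), c(60, 40))
  f1 <- assign_folds(lab, n_folds = 10, seed = 3)
  f2 <- assign_folds(lab, n_folds = 10, seed = 3)
  expect_identical(f1, f2)
  counts <- table(f1, lab)
  expect_true(all(counts[, "a"] == 6))
  expect_true(all(counts[, "b"] == 4))
})
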