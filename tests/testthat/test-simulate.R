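test_that("same design, config and seed reproduce identical arrays", {
  cfg <- quick_config(n_trials = 8, n_eeg = 8)
  d <- generate_design(cfg$task, 8, seed = 1)
  a <- generate_eeg(d, cfg, seed = 42)
  b <- generate_eeg(d, cfg, seed = 42)
  expect_identical(a$epochs$voltages, b$epochs$voltages)
  c <- generate_eeg(d, cfg, seed = 43)
  expect_false(identical(a$epochs$voltages, c$epochs$voltages))
})

test_that("epoch geometry and channel bookkeeping match the config", {
  cfg <- quick_config(n_trials = 4, n_eeg = 16)
  sim <- simulate_participant(cfg, 1)
  d <- dim(sim$epochs$voltages)
  expect_equal(d, c(4, 16 + 4, 3 * 512))
  expect_equal(range(sim$epochs$times), c(-1, 2 - 1 / 512))
  expect_equal(sum(sim$epochs$layout$type == "eeg"), 16)
  expect_setequal(sim$epochs$layout$name[sim$epochs$layout$type != "eeg"],
                  c("VEOG", "HEOG", "M1", "M2"))
  expect_equal(nrow(sim$design), 4)
})

test_that("an injected theta effect raises band power at its top channels", {
  # oracle: plain FFT band energy at the three highest-weighted channels,
  # compared between classes with a two-sample t-test
  cfg <- synthetic_config(
    n_trials = 400, n_eeg_channels = 32,
    effects = list(effect_spec(band = c(5, 5), window = c(0.1, 0.7),
                               amplitude = c(congruent = 0, incongruent = 25))),
    blink_prob = 0, hv_prob = 0, seed = 2)
  d <- generate_design(cfg$task, 400, seed = 1)
  ee <- generate_eeg(d, cfg, seed = 2)
  topo <- gaussian_topography(ee$epochs$layout, "midfrontal")
  top3 <- match(names(sort(topo, decreasing = TRUE))[1:3],
                ee$epochs$layout$name)
  bp <- band_power_oracle(ee$epochs, top3, c(4, 8), c(0.1, 0.7))
  tt <- t.test(bp[d$congruency == "incongruent"],
               bp[d$congruency == "congruent"])
  expect_lt(tt$p.value, 0.001)
  expect_gt(tt$statistic, 0)
})

test_that("blink transients exceed the rejection threshold on VEOG", {
  cfg <- quick_config(n_trials = 20, n_eeg = 8)
  cfg$blink_prob <- 1
  d <- generate_design(cfg$task, 20, seed = 1)
  ee <- generate_eeg(d, cfg, seed = 7)
  veog <- which(ee$epochs$layout$type == "veog")
  sel <- ee$epochs$times >= 0 & ee$epochs$times <= 0.8
  peaks <- apply(ee$epochs$voltages[, veog, sel], 1, max)
  expect_true(all(peaks > 100))
  expect_true(all(ee$truth$blink))
})

test_that("invalid effect windows and topographies are rejected", {
  cfg <- quick_config(n_trials = 4, n_eeg = 8)
  cfg$effects <- list(effect_spec(window = c(1.9, 2.5),
                                  amplitude = c(congruent = 0, incongruent = 1)))
  d <- generate_design(cfg$task, 4, seed = 1)
  expect_error(generate_eeg(d, cfg, seed = 1), "window outside epoch")

  cfg$effects <- list(effect_spec(topography = rep(1 / sqrt(64), 64),
                                  amplitude = c(congruent = 0, incongruent = 1)))
  expect_error(generate_eeg(d, cfg, seed = 1), "topography length")
})

test_that("decodability is chance at zero amplitude and grows with it", {
  # theta band-power features (direct FFT band energy per channel), decoded
  # with cross-validated LDA, over 20 seeds at three injected amplitudes
  mean_auc <- function(amplitude) {
    mean(vapply(1:20, function(s) {
      cfg <- quick_config(n_trials = 32, n_eeg = 8, amplitude = amplitude,
                          seed = s)
      sim <- simulate_participant(cfg, 1)
      eegs <- which(sim$epochs$layout$type == "eeg")
      feats <- vapply(eegs, function(ch)
        band_power_oracle(sim$epochs, ch, c(4, 8), c(0.1, 0.7)),
        numeric(32))
      crossval_decode(feats, sim$epochs$events$congruency, n_folds = 4,
                      seed = s)$auc
    }, numeric(1)))
  }
  a0 <- mean_auc(0); a1 <- mean_auc(10); a2 <- mean_auc(30)
  expect_equal(a0, 0.5, tolerance = 0.05 / 0.5)
  expect_gte(a1, a0 - 0.02)
  expect_gte(a2, a1 - 0.02)
  expect_gt(a2, 0.7) # a strong effect is clearly decodable
})

test_that("serialization round-trips epochs through disk", {
  cfg <- quick_config(n_trials = 4, n_eeg = 4)
  sim <- simulate_participant(cfg, 1)
  path <- file.path(tempdir(), "roundtrip")
  write_epochs(sim$epochs, path)
  back <- read_epochs(path)
  expect_equal(back$voltages, sim$epochs$voltages, ignore_attr = TRUE)
  expect_equal(back$events$congruency, sim$epochs$events$congruency)
  expect_equal(back$srate, 512)
})
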