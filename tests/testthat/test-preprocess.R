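test_that("band-pass keeps the passband, kills DC and the stopband", {
  fs <- 512
  ep <- toy_epochs(n_trials = 1, n_eeg = 2, fs = fs)
  t <- ep$times
  ep$voltages[1, 1, ] <- sin(2 * pi * 10 * t)        # passband
  ep$voltages[1, 2, ] <- sin(2 * pi * 100 * t)       # stopband
  out <- bandpass_filter(ep, 0.01, 50)
  expect_equal(sd(out$voltages[1, 1, ]), sd(ep$voltages[1, 1, ]),
               tolerance = 0.05)
  expect_lt(sd(out$voltages[1, 2, ]) / sd(ep$voltages[1, 2, ]), 0.10)

  ep$voltages[1, 1, ] <- 7 # constant offset
  out <- bandpass_filter(ep)
  expect_lt(abs(mean(out$voltages[1, 1, ])), 1e-6)

  expect_error(bandpass_filter(ep, 0.01, 300), "Nyquist")
})

test_that("re-referencing subtracts the reference average sample-wise", {
  ep <- toy_epochs(n_trials = 2, n_eeg = 3)
  set.seed(1)
  ep$voltages[] <- rnorm(length(ep$voltages))
  refs <- which(ep$layout$type == "ref")
  eegs <- which(ep$layout$type == "eeg")

  # refs identically zero: no change
  ep0 <- ep; ep0$voltages[, refs, ] <- 0
  out0 <- rereference(ep0)
  expect_equal(out0$voltages[, eegs, ], ep0$voltages[, eegs, ])

  # constant refs: every EEG channel shifted by -c
  epc <- ep; epc$voltages[, refs, ] <- 3
  outc <- rereference(epc)
  expect_equal(outc$voltages[, eegs, ], epc$voltages[, eegs, ] - 3)

  # general case: direct recomputation, references untouched
  out <- rereference(ep)
  m <- (ep$voltages[, refs[1], ] + ep$voltages[, refs[2], ]) / 2
  for (ch in eegs)
    expect_equal(out$voltages[, ch, ], ep$voltages[, ch, ] - m)
  expect_equal(out$voltages[, refs, ], ep$voltages[, refs, ])

  expect_error(rereference(ep, "NOPE"), "missing reference")
})

test_that("re-referencing twice with zero-mean references equals once", {
  ep <- toy_epochs(n_trials = 2, n_eeg = 3)
  set.seed(2)
  ep$voltages[] <- rnorm(length(ep$voltages))
  refs <- which(ep$layout$type == "ref")
  ep$voltages[, refs[2], ] <- -ep$voltages[, refs[1], ] # refs average to zero
  z1 <- rereference(ep)
  z2 <- rereference(z1)
  eegs <- which(ep$layout$type == "eeg")
  expect_equal(z2$voltages[, eegs, ], z1$voltages[, eegs, ], tolerance = 1e-12)
})

test_that("epoch segmentation uses a half-open sample-aligned window", {
  fs <- 512
  lay <- eeg_layout_64()[c(1, 2, 65), ]
  cont <- matrix(rnorm(3 * fs * 10), nrow = 3)
  ev <- c(2 * fs, 5 * fs)
  ep <- segment_epochs(cont, ev, lay, fs, t_min = -1, t_max = 2)
  expect_equal(dim(ep$voltages), c(2, 3, 1536))
  expect_equal(ep$voltages[1, , ep$times == 0], cont[, 2 * fs],
               ignore_attr = TRUE)
  expect_equal(ep$times[1], -1)

  ep2 <- segment_epochs(cont, 1, lay, fs, t_min = 0, t_max = 2)
  expect_equal(dim(ep2$voltages)[3], 2 * fs)

  expect_error(segment_epochs(cont, 100, lay, fs, -1, 2), "bounds")
})

test_that("two-pass artifact rejection applies thresholds inside 0-800 ms only", {
  ep <- toy_epochs(n_trials = 4, n_eeg = 3)
  veog <- which(ep$layout$type == "veog")
  # trial 1: blink at 400 ms; trial 2: clean; trial 3: EEG excursion at 900 ms
  # (outside the window, kept); trial 4: EEG excursion at 400 ms (dropped)
  ep$voltages[1, veog, ep$times >= 0.39 & ep$times <= 0.41] <- 150
  ep$voltages[3, 1, ep$times >= 0.89 & ep$times <= 0.91] <- 350
  ep$voltages[4, 2, ep$times >= 0.39 & ep$times <= 0.41] <- -350
  res <- reject_artifacts(ep)
  expect_equal(res$report$trials$keep, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(res$report$trials$reason, c("blink", NA, NA, "voltage"))
  expect_equal(res$report$fraction_blink, 0.25)
  expect_equal(res$report$fraction_voltage, 0.25)
  expect_equal(dim(res$epochs$voltages)[1], 2)

  # idempotence: a second pass on survivors drops nothing
  res2 <- reject_artifacts(res$epochs)
  expect_true(all(res2$report$trials$keep))

  lay_noveog <- ep$layout[ep$layout$type != "veog", ]
  bad <- eeg_epochs(ep$voltages[, ep$layout$type != "veog", , drop = FALSE],
                    lay_noveog, ep$times, ep$srate)
  expect_error(reject_artifacts(bad), "VEOG")
})

test_that("participant screening flags only extreme rejection fractions", {
  expect_equal(screen_participants(rep(0.1, 5)), integer(0))
  expect_equal(screen_participants(c(0.05, 0.06, 0.07)), integer(0))
  # a 64.5% participant against a low-rejection group is beyond 3 SD
  fr <- c(rep(0.06, 20), c(0.10, 0.15, 0.20), 0.645)
  expect_equal(screen_participants(fr), 24L)
  expect_warning(screen_participants(c(0.1, 0.2)), "skipped")
})

test_that("trial selection applies the RT-window and task-specific rules", {
  d <- generate_design("content_discrimination_1", 40, seed = 1)
  b <- generate_behavior(d, "content_discrimination_1",
                         behavior_params(miss_rate = 0), seed = 2)
  b$rt_ms[1] <- 90    # too fast
  b$rt_ms[2] <- 1600  # too slow
  b$rt_ms[3] <- NA; b$response[3] <- NA  # miss
  keep <- select_trials(b, "content_discrimination_1", "behavior_stats")
  expect_false(any(c(1, 2, 3) %in% keep))
  expect_true(all(setdiff(seq_len(40), c(1, 2, 3)) %in% keep))

  # decoding: auditory tasks keep correct only
  b$correct[5] <- FALSE
  expect_false(5 %in% select_trials(b, "content_discrimination_1", "decoding"))

  # RDM tasks keep errors for decoding
  d2 <- generate_design("vertical_rdm", 40, seed = 1)
  b2 <- generate_behavior(d2, "vertical_rdm", behavior_params(), seed = 2)
  b2$correct[7] <- FALSE
  expect_true(7 %in% select_trials(b2, "vertical_rdm", "decoding"))

  # oddball: only correct rejections survive for decoding
  d3 <- generate_design("volume_oddball", 400, seed = 1)
  b3 <- generate_behavior(d3, "volume_oddball", behavior_params(), seed = 3)
  keep3 <- select_trials(b3, "volume_oddball", "decoding")
  expect_true(all(!b3$oddball[keep3]))
  expect_true(all(b3$correct[keep3]))
})

test_that("class balancing undersamples to the minimum and never inflates", {
  lab <- rep(c("A", "B"), c(60, 40))
  kept <- balance_classes(lab, seed = 1)
  expect_equal(unname(table(lab[kept])), c(40, 40), ignore_attr = TRUE)

  lab2 <- rep(c("A", "B"), c(30, 30))
  kept2 <- balance_classes(lab2, seed = 1)
  expect_equal(sort(kept2), seq_len(60))

  expect_error(balance_classes(factor("A", levels = c("A", "B"))),
               "at least one")

  # joint cell balancing equalizes all four content x location cells
  cells <- rep(c("l.l", "l.r", "r.l", "r.r"), c(10, 20, 30, 40))
  kept3 <- balance_classes(rep("x", 100), seed = 2, cells = cells)
  expect_true(all(table(cells[kept3]) == 10))
  # deterministic given seed
  expect_identical(kept3, balance_classes(rep("x", 100), seed = 2, cells = cells))
})
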