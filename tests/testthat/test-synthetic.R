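test_that("MUAP templates meet amplitude, support and charge-balance invariants", {
  fs <- 48000
  cases <- list(c(amp = 500, dur = 10, ph = 3),
                c(amp = 200, dur = 5, ph = 2),
                c(amp = 1500, dur = 15, ph = 4),
                c(amp = 80, dur = 3, ph = 2))
  for (cs in cases) {
    set.seed(1)
    tpl <- makeMuapTemplate(cs["amp"], cs["dur"], cs["ph"], fs)
    expect_equal(length(tpl$waveform), round(cs["dur"] / 1000 * fs),
                 ignore_attr = TRUE)
    ptp <- max(tpl$waveform) - min(tpl$waveform)
    expect_lt(abs(ptp - cs["amp"]) / cs["amp"], 0.01)
    expect_lt(abs(sum(tpl$waveform)) / ptp, 0.01)
    expect_lt(abs(mean(tpl$waveform)), 0.01 * cs["amp"])
  }
  # determinism given the RNG state
  t1 <- withr::with_seed(5, makeMuapTemplate(300, 8, 3, fs))
  t2 <- withr::with_seed(5, makeMuapTemplate(300, 8, 3, fs))
  expect_identical(t1$waveform, t2$waveform)
  # amplitude ordering is forced by construction
  set.seed(2)
  small <- makeMuapTemplate(200, 5, 3, fs)
  large <- makeMuapTemplate(1500, 15, 3, fs)
  expect_lt(diff(range(small$waveform)), diff(range(large$waveform)))
  expect_error(makeMuapTemplate(-10, 5, 3, fs), "amplitude")
  expect_error(makeMuapTemplate(100, 0, 3, fs), "duration")
  expect_error(makeMuapTemplate(100, 5, 3, 16000), "Nyquist|band|fs")
})

test_that("motor unit pools follow the class physiology orderings", {
  phys <- defaultPhysiology()
  set.seed(10)
  stats <- lapply(diagnosisLevels(), function(cl) {
    amps <- durs <- thrs <- numeric(100)
    for (i in 1:100) {
      pool <- sampleMotorUnitPool(phys, cl, 48000)
      amps[i] <- mean(vapply(pool, function(u) u$template$amplitude, 1))
      durs[i] <- mean(vapply(pool, function(u) u$template$duration, 1))
      thrs[i] <- median(vapply(pool, function(u) u$threshold, 1))
      expect_true(all(vapply(pool, function(u) u$threshold, 1) >= 0))
      expect_true(all(vapply(pool, function(u) u$threshold, 1) <= 1))
    }
    c(amp = mean(amps), dur = mean(durs), thr = median(thrs))
  })
  names(stats) <- diagnosisLevels()
  expect_lt(stats$M["amp"], stats$NL["amp"])
  expect_lt(stats$NL["amp"], stats$N["amp"])
  expect_lt(stats$M["dur"], stats$NL["dur"])
  expect_lt(stats$NL["dur"], stats$N["dur"])
  expect_lt(stats$M["thr"], stats$NL["thr"])
  expect_lt(stats$NL["thr"], stats$N["thr"])
})

test_that("degenerate physiology with a point amplitude range is honoured", {
  pp <- classPhysiology(amplitude = c(250, 250), duration = c(5, 5),
                        poolSize = c(3, 3), thresholdMax = 0.5)
  set.seed(3)
  pool <- sampleMotorUnitPool(pp, "M", 48000)
  amps <- vapply(pool, function(u) {
    diff(range(u$template$waveform))
  }, numeric(1))
  expect_true(all(abs(amps - 250) / 250 < 0.01))
  expect_error(classPhysiology(amplitude = c(0, 0), duration = c(5, 5),
                               poolSize = c(3, 3), thresholdMax = 0.5),
               "positive")
  expect_error(classPhysiology(amplitude = c(400, 100), duration = c(5, 5),
                               poolSize = c(3, 3), thresholdMax = 0.5),
               "range")
})

test_that("renderSignal honours drive, noise level and firing statistics", {
  set.seed(2)
  tpl <- makeMuapTemplate(300, 8, 3, 48000)
  pool <- list(list(template = tpl, threshold = 0, rate = 10, isiCv = 0))
  # nothing recruited, no noise: exact zeros
  sig0 <- renderSignal(pool, drive = 0, duration = 1, fs = 48000,
                       noiseRms = 0)
  expect_identical(samples(sig0), numeric(48000))
  # regular 10 Hz train at full drive: floor(2 * 10) +/- 1 onsets, 100 ms apart
  set.seed(3)
  sig <- renderSignal(pool, drive = 1, duration = 2, fs = 48000,
                      noiseRms = 0)
  xc <- as.numeric(stats::filter(samples(sig), rev(tpl$waveform), sides = 1))
  thr <- max(xc, na.rm = TRUE) * 0.5
  pk <- which(xc > thr & xc >= c(-Inf, head(xc, -1)) & xc >= c(xc[-1], -Inf))
  pk <- pk[c(TRUE, diff(pk) > 100)]
  expect_lte(abs(length(pk) - 20), 1)
  expect_equal(unique(diff(pk)), 0.1 * 48000, tolerance = 1e-6)
  # firing rate scales with drive: ~5 Hz effective at drive 0.5
  set.seed(4)
  sig5 <- renderSignal(pool, drive = 0.5, duration = 2, fs = 48000,
                       noiseRms = 0)
  xc5 <- as.numeric(stats::filter(samples(sig5), rev(tpl$waveform), sides = 1))
  pk5 <- which(xc5 > max(xc5, na.rm = TRUE) * 0.5 &
                 xc5 >= c(-Inf, head(xc5, -1)) & xc5 >= c(xc5[-1], -Inf))
  pk5 <- pk5[c(TRUE, diff(pk5) > 100)]
  expect_lte(abs(length(pk5) - 10), 1)
  expect_error(renderSignal(pool, drive = 2, duration = 1, fs = 48000),
               "drive")
  expect_error(renderSignal(pool, drive = 1, duration = 1, fs = 12000),
               "Nyquist")
})

test_that("band-limited noise stays in the 20 Hz - 10 kHz recording band", {
  set.seed(4)
  nz <- emgdx:::.bandlimitedNoise(96000, 48000, 25)
  expect_equal(sqrt(mean(nz^2)), 25, tolerance = 1e-3)
  sp <- Mod(fft(nz))^2
  fr <- (seq_along(nz) - 1) / length(nz) * 48000
  half <- fr <= 24000
  inBand <- half & fr >= 20 & fr <= 10000
  expect_gte(sum(sp[inBand]) / sum(sp[half]), 0.95)
})

test_that("simulateCohort is reproducible, extensible and shaped as requested", {
  c1 <- simulateCohort(nPerClass = 1, signalsPerPatient = c(1, 1),
                       durationRange = c(0.5, 0.6), seed = 9)
  expect_equal(nPatients(c1), 3)
  expect_equal(nSignals(c1), 3)
  c2 <- simulateCohort(nPerClass = 1, signalsPerPatient = c(1, 1),
                       durationRange = c(0.5, 0.6), seed = 9)
  expect_identical(lapply(cohortSignals(c1), samples),
                   lapply(cohortSignals(c2), samples))
  # counter-based child seeds: growing the cohort leaves earlier
  # patients' waveforms untouched
  c3 <- simulateCohort(nPerClass = 2, signalsPerPatient = c(1, 1),
                       durationRange = c(0.5, 0.6), seed = 9)
  ids1 <- vapply(cohortSignals(c1), signalId, character(1))
  ids3 <- vapply(cohortSignals(c3), signalId, character(1))
  for (id in ids1) {
    expect_identical(samples(cohortSignals(c1)[[match(id, ids1)]]),
                     samples(cohortSignals(c3)[[match(id, ids3)]]))
  }
  # per-patient counts within the requested range; diagnosis consistency
  fx <- fixtureCohort()
  pt <- patientTable(fx$cohort)
  expect_true(all(pt$n_signals >= 2 & pt$n_signals <= 3))
  expect_equal(as.vector(table(pt$diagnosis)), c(3, 3, 3))
})

test_that("simulateRaterPanel samples labels from its confusion spec", {
  fx <- fixtureCohort()
  ident <- diag(3); dimnames(ident) <- list(diagnosisLevels(),
                                            diagnosisLevels())
  pan <- simulateRaterPanel(fx$cohort, ident, nRaters = 3,
                            jitterConcentration = Inf, seed = 5)
  lab <- raterLabels(pan)
  expect_true(all(lab$label == lab$true_label))
  # uniform rows: accuracy near 1/3 over >= 900 draws
  unif <- matrix(1 / 3, 3, 3, dimnames = dimnames(ident))
  panU <- simulateRaterPanel(fx$cohort, unif, nRaters = 30,
                             jitterConcentration = Inf, seed = 6)
  labU <- raterLabels(panU)
  expect_gt(nrow(labU), 900)
  expect_equal(mean(labU$label == labU$true_label), 1 / 3, tolerance = 0.15)
  bad <- ident; bad[1, 1] <- 0.5
  expect_error(simulateRaterPanel(fx$cohort, bad), "stochastic")
})
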