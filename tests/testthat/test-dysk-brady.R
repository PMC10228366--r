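# Dyskinesia regions/scores and bradykinesia movement segmentation/scoring.

test_that("movement segmentation counts injected bursts and recovers their peak speeds", {
  fs <- FS
  set.seed(51)
  n <- round(120 * fs)
  g <- matrix(rnorm(3 * n, 0, 1), n, 3)
  starts <- round(seq(5, 110, length.out = 10) * fs)
  peaks <- runif(10, 80, 160)
  for (k in 1:10) {
    ns <- round(0.6 * fs)
    pulse <- peaks[k] * sin(pi * seq_len(ns) / ns)^2
    g[starts[k] + seq_len(ns), 1] <- g[starts[k] + seq_len(ns), 1] + pulse
  }
  ev <- segmentMovements(g, fs)
  expect_lt(abs(nrow(ev) - 10), 2)
  # each detected event matched to its generated pulse: peaks within 10%
  relErr <- vapply(seq_len(nrow(ev)), function(i) {
    k <- which.min(abs(starts - ev$start_sample[i]))
    abs(ev$peak_dps[i] - peaks[k]) / peaks[k]
  }, numeric(1))
  expect_lt(median(relErr), 0.10)
  expect_equal(nrow(segmentMovements(matrix(0, n, 3), fs)), 0)
  # events outside the eligible mask are dropped
  mask <- rep(TRUE, n); mask[seq_len(round(60 * fs))] <- FALSE
  ev2 <- segmentMovements(g, fs, eligible = mask)
  expect_true(all(ev2$start_sample > 60 * fs))
  expect_lt(nrow(ev2), nrow(ev))
})

test_that("the normative threshold is the 5th percentile and order-invariant", {
  set.seed(52)
  speeds <- runif(2000, 50, 150)
  thr <- fitNormative(speeds)
  expect_lt(abs(thr - 55), 1.5)  # analytic 5th percentile of U(50,150)
  expect_equal(fitNormative(sample(speeds)), thr)
  expect_equal(fitNormative(rep(77, 150)), 77)
  expect_error(fitNormative(runif(50)), "at least 100")
})

test_that("bradykinesia score is the percentage of sub-norm movements", {
  expect_equal(bradykinesiaScore(c(10, 20, 30), 50), 100)
  expect_equal(bradykinesiaScore(c(60, 70), 50), 0)
  expect_equal(bradykinesiaScore(c(10, 90), 50), 50)
  expect_true(is.na(bradykinesiaScore(numeric(0), 50)))
})

test_that("slowing the movement generator raises the bradykinesia score", {
  mkPeaks <- function(mult, seed) {
    prof <- subjectProfile(gaitRom = 42, gaitCadence = 110, swingCv = 0.03,
                          speedMult = mult)
    sch <- makeSchedule(0.25)
    sch$bouts <- data.frame(type = "free_movement", start_s = 0, duration_s = 900)
    sch$stateBins <- "ON"; sch$totalS <- 900
    sim <- simulateRecording(prof, sch, seed = seed)
    ev <- segmentMovements(imuStream(sim$recording, "left_wrist")[, 4:6], FS)
    ev$peak_dps
  }
  fast <- mkPeaks(1.0, 53); slow <- mkPeaks(0.5, 53)
  thr <- fitNormative(c(fast, mkPeaks(1.0, 54)))
  expect_gt(bradykinesiaScore(slow, thr), bradykinesiaScore(fast, thr))
})

test_that("dyskinetic regions are flagged from posteriors, scored monotonically in gain, and never flagged for controls", {
  mkSim <- function(gain, seed = 55) {
    prof <- subjectProfile(gaitRom = 42, gaitCadence = 110, swingCv = 0.03,
                          dyskGain = gain, speedMult = 1)
    sch <- makeSchedule(0.5)
    sch$bouts <- data.frame(type = "rest_sit", start_s = 0, duration_s = 1800)
    sch$stateBins <- "ON"; sch$totalS <- 1800
    simulateRecording(prof, sch, seed = seed)
  }
  sev <- vapply(c(8, 15, 25), function(g) {
    sim <- mkSim(g)
    wins <- assignBins(segmentWindows(sim$recording, 4))
    labels <- sim$truth$windows$label
    p <- as.numeric(labels == "Dyskinetic")  # posterior stand-in from truth
    reg <- detectDyskineticRegions(sim$recording, wins, labels, p)
    expect_true(all(reg$dyskinetic))
    mean(reg$severity)
  }, numeric(1))
  expect_true(all(diff(sev) > 0))

  # control: resting only, zero posterior -> not flagged, severity 0
  simC <- mkSim(0, seed = 56)
  winsC <- assignBins(segmentWindows(simC$recording, 4))
  regC <- detectDyskineticRegions(simC$recording, winsC,
                                  simC$truth$windows$label,
                                  rep(0, nrow(winsC)))
  expect_true(all(!regC$dyskinetic))
  expect_true(all(regC$severity == 0))

  # fully-walking interval is excluded
  regW <- detectDyskineticRegions(simC$recording, winsC,
                                  rep("Walking", nrow(winsC)),
                                  rep(0, nrow(winsC)))
  expect_true(all(regW$excluded))
})

test_that("30-minute dyskinesia score averages scored regions and marks empty bins", {
  reg <- data.frame(interval = 1:6, start_s = (0:5) * 300,
                    excluded = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                    dyskinetic = TRUE, p_dysk = 0.9, band_rms = 10,
                    severity = c(1, 3, NA, 2, 2, 2))
  sc <- dyskinesiaScore30(reg)
  expect_equal(sc$dyskinesia_score, mean(c(1, 3, 2, 2, 2)))
  regE <- reg; regE$excluded <- TRUE
  expect_true(is.na(dyskinesiaScore30(regE)$dyskinesia_score))
})
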