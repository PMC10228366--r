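# Synthetic-data generator: determinism, label consistency, physical
# plausibility, schedule structure, cohort plumbing.

test_that("recordings respect device full scales, are deterministic, and differ across seeds", {
  prof <- testPatientProfile()
  sch <- makeSchedule(0.25, offBins = 1)
  sim1 <- simulateRecording(prof, sch, seed = 71)
  sim2 <- simulateRecording(prof, sch, seed = 71)
  sim3 <- simulateRecording(prof, sch, seed = 72)
  expect_identical(sim1$recording@streams, sim2$recording@streams)
  expect_false(identical(sim1$recording@streams, sim3$recording@streams))
  for (p in pdmotor:::IMU_POSITIONS) {
    m <- imuStream(sim1$recording, p)
    expect_lte(max(abs(m[, 1:3])), 8)
    expect_lte(max(abs(m[, 4:6])), 2000)
    expect_lte(max(abs(m[, 7:9])), 16)
  }
  expect_s4_class(sim1$recording, "IMURecording")  # validity ran
})

test_that("control profiles produce no symptom ground truth", {
  sim <- simulateRecording(testControlProfile(), makeSchedule(0.5, isControl = TRUE),
                           seed = 73)
  expect_null(sim$truth$fogEvents)
  expect_true(all(sim$truth$windows$label %in% c("Walking", "Resting", "Other")))
  tb <- sim$truth$bins
  expect_true(all(tb[, grep("tremor_amp", names(tb))] == 0))
  expect_true(all(tb$dysk_eff == 0))
  expect_true(all(!tb$off))
  expect_error(subjectProfile(dyskGain = 5, isControl = TRUE))
})

test_that("tremor bouts concentrate gyro power in the 3.5-8 Hz band", {
  prof <- subjectProfile(
    tremorGain = setNames(c(40, 0, 0, 0), pdmotor:::LIMBS),
    tremorFreq = setNames(rep(5, 4), pdmotor:::LIMBS),
    gaitRom = 40, gaitCadence = 105, swingCv = 0.03, speedMult = 1)
  sch <- makeSchedule(0.25, offBins = 1)
  # many short rest bouts: tremor is intermittent per bout, expected in ~80%
  sch$bouts <- data.frame(type = "rest_sit", start_s = seq(0, 840, by = 60),
                          duration_s = 60)
  sch$totalS <- 900
  sim <- simulateRecording(prof, sch, seed = 74)
  lab <- sim$truth$windows$label
  expect_gt(mean(lab == "Tremor"), 0.5)
  expect_true(all(lab %in% c("Tremor", "Resting")))
  # spectrum over a tremor-labeled bout
  tw <- sim$truth$windows$start_s[lab == "Tremor"][1]
  g <- imuStream(sim$recording, "left_wrist")[round(tw * FS) + 1:round(30 * FS), 4:6]
  pg <- pdmotor:::triAxialSpectrum(g, FS)
  inband <- sum(pg$power[pg$freq >= 3.5 & pg$freq <= 8])
  # >= 80% of oscillation power inside the tremor band (harmonic spills above)
  expect_gt(inband / sum(pg$power), 0.8)
})

test_that("walking bouts carry detectable periodicity at the commanded cadence", {
  sim <- simulateRecording(testControlProfile(), makeSchedule(0.5, isControl = TRUE),
                           seed = 75)
  walkWins <- sim$truth$windows[sim$truth$windows$label == "Walking", ]
  expect_gt(nrow(walkWins), 10)
  gz <- imuStream(sim$recording, "left_ankle")[, "gz"]
  i0 <- round(walkWins$start_s[1] * FS) + 1
  seg <- gz[i0:(i0 + round(16 * FS))]
  ac <- acf(seg, lag.max = round(2 * FS), plot = FALSE)$acf[-1]
  strideLag <- which.max(ac[round(0.5 * FS):round(2 * FS)]) + round(0.5 * FS) - 1
  cadHat <- 120 / (strideLag / FS)
  # autocorrelation peak within 5% of commanded cadence (110-ish for controls)
  prof <- testControlProfile()
  expect_lt(abs(cadHat - 112) / 112, 0.08)
})

test_that("schedules tile the session in 4-s multiples and switch state only on 30-min boundaries", {
  set.seed(76)
  sch <- makeSchedule(2)
  b <- sch$bouts
  expect_equal(b$start_s[1], 0)
  expect_equal(b$start_s + b$duration_s, c(b$start_s[-1], sch$totalS))
  expect_true(all(b$duration_s %% 4 == 0))
  expect_length(sch$stateBins, 4)
  # bouts never span a 30-min boundary
  expect_true(all(floor(b$start_s / 1800) ==
                  floor((b$start_s + b$duration_s - 1e-9) / 1800)))
  schC <- makeSchedule(2, isControl = TRUE)
  expect_true(all(schC$stateBins == "ON"))
})

test_that("cohort plans are reproducible, size-correct, and yield consistent annotations", {
  plan <- simulateCohort(nPatients = 3, nControls = 2, days = 2,
                         hoursPerDay = 0.5, seed = 77)
  plan2 <- simulateCohort(nPatients = 3, nControls = 2, days = 2,
                          hoursPerDay = 0.5, seed = 77)
  expect_identical(plan$seeds, plan2$seeds)
  expect_equal(nrow(plan$subjects), 5)
  expect_true(all(vapply(plan$profiles[4:5], function(p) p$isControl, logical(1))))

  ann <- cohortAnnotations(plan)
  expect_equal(nrow(ann), 5 * 2 * 1)  # subjects x days x bins(0.5 h)
  ctrl <- ann[ann$subject %in% c("C01", "C02"), ]
  expect_true(all(ctrl$diary_state == "ON"))
  expect_true(all(ctrl[, grep("updrs|aims", names(ctrl))] == 0))

  gt <- groundTruthReport(plan)
  expect_equal(nrow(gt), 5 * 2 * 1)
  expect_true(all(gt$off == (gt$state == "OFF")))

  # recordings regenerate bit-identically from the plan
  r1 <- cohortRecording(plan, "P01", 1)
  r2 <- cohortRecording(plan, 1, 1)
  expect_identical(r1$recording@streams, r2$recording@streams)
})

test_that("a written mini-dataset round-trips through the recording reader", {
  dir <- withr::local_tempdir()
  plan <- simulateCohort(nPatients = 1, nControls = 0, days = 1,
                         hoursPerDay = 2 / 60, seed = 78)
  writeCohort(plan, dir)
  rec <- readRecording(file.path(dir, "P01_day1", "manifest.yaml"))
  orig <- cohortRecording(plan, 1, 1)$recording
  expect_equal(length(rec), length(orig))
  expect_identical(imuStream(rec, "left_ankle"), imuStream(orig, "left_ankle"))
  expect_true(file.exists(file.path(dir, "annotations.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
})
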