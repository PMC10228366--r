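# Walking-region merging, step detection against simulator ground truth,
# gait features, gait score, freeze index and FoG detection.

# one walking bout flanked by quiet standing, via the simulator
walkFixture <- function(cadence = 105, rom = 40, seed = 41, walkS = 80) {
  prof <- subjectProfile(gaitRom = rom, gaitCadence = cadence, swingCv = 0.03,
                        isControl = TRUE)
  sch <- makeSchedule(walkS / 3600 + 0.05, isControl = TRUE)
  sch$bouts <- data.frame(type = c("stand", "walk", "stand"),
                          start_s = c(0, 8, 8 + walkS),
                          duration_s = c(8, walkS, 172 - walkS))
  sch$totalS <- 180
  simulateRecording(prof, sch, seed = seed)
}

test_that("walking regions merge runs, bridge 1-window gaps, and drop short runs", {
  r <- mergeWalking(c("Walking", "Walking", "Walking"), 4)
  expect_equal(nrow(r), 1)
  expect_equal(r$end_s - r$start_s, 12)

  r2 <- mergeWalking(c("Walking", "Resting", "Walking"), 4)
  expect_equal(nrow(r2), 1)  # gap bridged

  r3 <- mergeWalking(c("Resting", "Walking", "Resting"), 4)
  expect_equal(nrow(r3), 0)  # 4 s < 8 s minimum

  r4 <- mergeWalking(c("Walking", "Walking", "Resting", "Resting",
                       "Walking", "Walking", "Walking"), 4)
  expect_equal(nrow(r4), 2)  # 2-window gap is not bridged
})

test_that("step detection recovers the generated cycle count and RS timing", {
  sim <- walkFixture(seed = 42)
  truth <- sim$truth$steps
  gz <- imuStream(sim$recording, "left_ankle")[, "gz"]
  wins <- segmentWindows(sim$recording, 4)
  reg <- data.frame(i0 = round(8 * FS) + 1, i1 = round(88 * FS))
  st <- detectSteps(gz[reg$i0:reg$i1], FS)
  genL <- truth[truth$side == "left_ankle", ]
  expect_lt(abs(nrow(st) - nrow(genL)), 2)  # n detected within +-1 of generated
  expect_true(all(st$tc < st$rs & st$rs < st$ic))

  # detected RS times match generated mid-swing times within 50 ms
  rsDet <- (st$rs + reg$i0 - 1) / FS
  match <- vapply(rsDet, function(t) min(abs(genL$rs_s - t)), numeric(1))
  expect_lt(median(match), 0.05)

  expect_equal(nrow(detectSteps(rep(0, 2000), FS)), 0)
})

test_that("gait features recover cadence within 5% and RoM within 10%", {
  for (seed in c(43, 44)) {
    sim <- walkFixture(cadence = 100, rom = 40, seed = seed)
    gz <- imuStream(sim$recording, "left_ankle")[, "gz"]
    seg <- gz[(round(8 * FS) + 1):round(88 * FS)]
    st <- detectSteps(seg, FS)
    f <- computeGaitFeatures(st, seg, FS)
    expect_lt(abs(f$cadence - 100) / 100, 0.05)
    expect_lt(abs(f$rom_deg - 40) / 40, 0.10)
  }
  # identical swing times -> zero variability
  st0 <- data.frame(tc = c(100, 200, 300), rs = c(130, 230, 330),
                    ic = c(160, 260, 360))
  f0 <- computeGaitFeatures(st0, sin(2 * pi * (1:400) / 100), FS)
  expect_equal(f0$swing_cv, 0)
  expect_null(computeGaitFeatures(st0[1, ], rep(0, 400), FS))
})

test_that("the gait score decreases in RoM, stays in [0,4], and is low for healthy gait", {
  m <- defaultGaitModel()
  expect_lt(m$coef$rom_deg, 0)
  expect_equal(which.max(abs(unlist(m$coef))), 1L, ignore_attr = TRUE)

  healthy <- list(rom_deg = 43, cadence = 112, swing_cv = 0.03)
  expect_lte(gaitScore(healthy, m), 0.5)

  worse <- healthy; worse$rom_deg <- healthy$rom_deg / 2
  expect_gt(gaitScore(worse, m), gaitScore(healthy, m))

  set.seed(45)
  for (i in 1:50) {
    f <- list(rom_deg = runif(1, 2, 60), cadence = runif(1, 40, 140),
              swing_cv = runif(1, 0, 0.4))
    s <- gaitScore(f, m)
    expect_gte(s, 0); expect_lte(s, 4)
  }
})

test_that("freeze index separates freeze-band from locomotor-band signals", {
  n <- round(4 * FS); t <- seq_len(n) / FS
  g5 <- outer(50 * sin(2 * pi * 5 * t), c(0.7, 0.5, 0.4))
  expect_gt(freezeIndex(g5, FS)$fi, 10)
  g1 <- outer(50 * sin(2 * pi * 1 * t), c(0.7, 0.5, 0.4))
  expect_lt(freezeIndex(g1, FS)$fi, 0.1)
  expect_equal(freezeIndex(matrix(0, n, 3), FS)$fi, 0)
})

test_that("FoG detection fires on pre-walk trembling bursts and not on clean initiations or wrist tremor", {
  mkSim <- function(fogPropensity, tremorWrist = 0, seed = 46) {
    prof <- subjectProfile(
      tremorGain = setNames(c(tremorWrist, 0, 0, 0), pdmotor:::LIMBS),
      tremorFreq = setNames(rep(5, 4), pdmotor:::LIMBS),
      gaitRom = 40, gaitCadence = 105, swingCv = 0.03,
      fogPropensity = fogPropensity, speedMult = 1)
    sch <- makeSchedule(0.5, offBins = 1)
    simulateRecording(prof, sch, seed = seed)
  }
  simF <- mkSim(1)  # always freezes before walking (OFF bin)
  rec <- simF$recording
  wins <- assignBins(segmentWindows(rec, 4))
  labels <- simF$truth$windows$label
  fog <- detectFog(rec, wins, labels)
  nTrue <- nrow(simF$truth$fogEvents)
  expect_gte(nTrue, 1)
  expect_equal(nrow(fog$events), nTrue)
  expect_equal(fog$ratio, 1)

  simC <- mkSim(0, seed = 47)  # clean initiations only
  fogC <- detectFog(simC$recording, assignBins(segmentWindows(simC$recording, 4)),
                    simC$truth$windows$label)
  expect_equal(nrow(fogC$events), 0)
  expect_true(is.na(fogC$ratio) || fogC$ratio == 0)
})
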