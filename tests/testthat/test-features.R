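test_that("tri-axial energy matches its definition, axis symmetries, and a brute-force oracle", {
  expect_equal(triAxialEnergy(cbind(c(3, 0), c(4, 0), c(0, 0))), 25)
  expect_equal(triAxialEnergy(matrix(0, 10, 3)), 0)
  expect_error(triAxialEnergy(list(1:3, 1:3, 1:4)), "equal-length")

  set.seed(4)
  w <- matrix(rnorm(238 * 3), 238, 3)
  oracle <- 0
  for (i in 1:238) for (k in 1:3) oracle <- oracle + w[i, k]^2
  expect_equal(triAxialEnergy(w), oracle, tolerance = 1e-9)
  # invariant under axis permutation and sign flips
  expect_equal(triAxialEnergy(w[, c(3, 1, 2)]), oracle)
  w2 <- w; w2[, 2] <- -w2[, 2]
  expect_equal(triAxialEnergy(w2), oracle)
})

test_that("band splitting routes power to the right component", {
  n <- round(10 * FS); t <- seq_len(n) / FS
  pwr <- function(x) sum(x^2)
  lowSig <- sin(2 * pi * 1 * t)
  sp <- splitBands(lowSig, FS, 3)
  expect_gt(pwr(sp$low) / pwr(lowSig), 0.95)
  highSig <- sin(2 * pi * 6 * t)
  sp2 <- splitBands(highSig, FS, 3)
  expect_gt(pwr(sp2$high) / pwr(highSig), 0.95)
  # components reconstruct the input
  expect_equal(sp$low + sp$high, lowSig, tolerance = 1e-8)
  dc <- rep(2, n)
  sp3 <- splitBands(dc, FS, 3)
  expect_equal(sp3$low, dc, tolerance = 1e-6)
  expect_lt(max(abs(sp3$high)), 1e-6)
  expect_error(splitBands(lowSig, FS, 40), "Nyquist")
})

test_that("time-domain features match direct formula oracles", {
  m <- matrix(2, 238, 9, dimnames = list(NULL, pdmotor:::IMU_CHANNELS))
  f <- timeDomainFeatures(m, FS)
  expect_equal(unname(f["ax_mean"]), 2)
  expect_equal(unname(f["ax_sd"]), 0)
  expect_equal(unname(f["jerk_rms"]), 0)

  set.seed(5)
  m2 <- matrix(rnorm(238 * 9), 238, 9, dimnames = list(NULL, pdmotor:::IMU_CHANNELS))
  f2 <- timeDomainFeatures(m2, FS)
  expect_equal(unname(f2["gy_mean"]), mean(m2[, "gy"]), tolerance = 1e-12)
  expect_equal(unname(f2["gy_sd"]), sd(m2[, "gy"]), tolerance = 1e-12)
  expect_equal(unname(f2["gy_energy"]), sum(m2[, "gy"]^2), tolerance = 1e-9)
  d <- diff(m2[, 1:3]) * FS
  expect_equal(unname(f2["jerk_rms"]), sqrt(mean(d^2)), tolerance = 1e-12)
})

test_that("frequency features put sinusoid power in the right bin and satisfy Parseval", {
  g <- sineWindow(5, 10, seconds = 4, axes = c(1, 0, 0))
  bins <- defaultFrequencyBins(FS)
  e <- frequencyDomainFeatures(g, FS, bins)
  expect_gt(e["gyro_band3"] / sum(e), 0.95)  # 5 Hz lives in (3-8]

  # Parseval: bin energies sum to total spectral power (per-axis spectra)
  set.seed(6)
  g2 <- matrix(rnorm(238 * 3), 238, 3)
  e2 <- frequencyDomainFeatures(g2, FS, bins)
  tot <- sum(periodogramHann(g2[, 1], FS)$power) +
    sum(periodogramHann(g2[, 2], FS)$power) +
    sum(periodogramHann(g2[, 3], FS)$power)
  expect_equal(sum(e2), tot, tolerance = 1e-6)

  expect_true(all(frequencyDomainFeatures(matrix(0, 238, 3), FS, bins) == 0))

  # white noise: energies proportional to bin widths (Monte Carlo over 100 windows)
  set.seed(7)
  acc <- 0
  for (i in 1:100) acc <- acc + frequencyDomainFeatures(matrix(rnorm(238 * 3), 238, 3), FS, bins)
  widths <- bins$hi - bins$lo
  expect_equal(as.numeric(acc / sum(acc)), widths / sum(widths), tolerance = 0.05)
})

test_that("the feature table has the fixed schema, >140 features, and is deterministic", {
  schema <- featureSchema()
  expect_gt(length(schema), 140)
  rec <- makeRecording(120)
  ft <- buildFeatureTable(rec)
  expect_equal(nrow(ft), 30)
  expect_equal(names(ft), c("window_start_s", schema))
  expect_true(all(is.finite(as.matrix(ft))))
  ft2 <- buildFeatureTable(makeRecording(120))
  expect_identical(ft, ft2)

  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  man <- yaml::read_yaml(paste0(path, ".schema.yaml"))
  expect_equal(unlist(man$features), schema)
  expect_equal(nrow(read.csv(path)), nrow(ft))
})

test_that("vectorized table features agree with the per-window operations", {
  rec <- makeRecording(20, seed = 8)
  ft <- buildFeatureTable(rec)
  wins <- segmentWindows(rec, 4)
  w3 <- windowMatrix <- pdmotor:::windowMatrix(rec, "left_ankle", wins[3, ])
  td <- timeDomainFeatures(w3, FS)
  expect_equal(ft$left_ankle_gz_mean[3], unname(td["gz_mean"]), tolerance = 1e-12)
  expect_equal(ft$left_ankle_gz_sd[3], unname(td["gz_sd"]), tolerance = 1e-9)
  expect_equal(ft$left_ankle_jerk_rms[3], unname(td["jerk_rms"]), tolerance = 1e-9)
  fd <- frequencyDomainFeatures(w3[, 4:6], FS)
  expect_equal(ft$left_ankle_gyro_band3[3], unname(fd["gyro_band3"]), tolerance = 1e-9)
  # identical gyro magnitudes across limbs give correlation 1
  streams <- makeStreams(round(20 * FS))
  streams$right_wrist[, 4:6] <- streams$left_wrist[, 4:6]
  rec2 <- IMURecording("x", streams, FS)
  ft2 <- buildFeatureTable(rec2)
  expect_true(all(abs(ft2$cor_left_wrist_right_wrist - 1) < 1e-9))
})
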