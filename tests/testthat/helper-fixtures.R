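# Shared fixtures: small recordings and helpers built in code at test time.

FS <- 59.5

# a minimal valid 5-stream list of constant/noise signals
makeStreams <- function(n, fs = FS, seed = 1) {
  set.seed(seed)
  streams <- lapply(pdmotor:::IMU_POSITIONS, function(p) {
    m <- cbind(matrix(rnorm(n * 3, 0, 0.02), n, 3),
               matrix(rnorm(n * 3, 0, 1), n, 3),
               matrix(rnorm(n * 3, 0, 0.005), n, 3))
    m[, 2] <- m[, 2] + 1  # gravity on Y
    colnames(m) <- pdmotor:::IMU_CHANNELS
    m
  })
  names(streams) <- pdmotor:::IMU_POSITIONS
  streams
}

makeRecording <- function(seconds = 60, fs = FS, seed = 1) {
  IMURecording("test", makeStreams(round(seconds * fs), fs, seed), fs)
}

# tri-axial sinusoid window helper (gyro-like)
sineWindow <- function(freq, amp, seconds = 3, fs = FS, axes = c(1, 0, 0),
                       noiseSd = 0) {
  n <- round(seconds * fs)
  t <- seq_len(n) / fs
  outer(amp * sin(2 * pi * freq * t), axes) +
    matrix(rnorm(3 * n, 0, noiseSd), n, 3)
}

# small, quick patient/control profiles for module tests
testPatientProfile <- function(...) {
  subjectProfile(
    tremorGain = setNames(c(35, 0, 20, 0), pdmotor:::LIMBS),
    tremorFreq = setNames(c(5, 5, 4.5, 5.5), pdmotor:::LIMBS),
    gaitRom = 38, gaitCadence = 104, swingCv = 0.05,
    dyskGain = 16, fogPropensity = 0.9, speedMult = 0.85, ...)
}

testControlProfile <- function() {
  subjectProfile(gaitRom = 43, gaitCadence = 112, swingCv = 0.03,
                 isControl = TRUE)
}

featureCols <- function(ft) {
  setdiff(names(ft), c("subject", "day", "bin", "label", "posture", "state",
                       "window_start_s"))
}
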