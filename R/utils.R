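#' @importFrom stats fft rnorm runif sd var quantile median cor aov t.test
#'   p.adjust qnorm setNames complete.cases predict coef lm approx
#' @importFrom utils head tail read.csv write.csv
NULL

# Device constants: five body positions, nominal sampling rate and IMU full
# scales (accelerometer g, gyroscope deg/s, magnetometer gauss).
IMU_POSITIONS <- c("left_wrist", "right_wrist", "left_ankle", "right_ankle", "waist")
IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
IMU_FULL_SCALE <- c(accel_g = 8, gyro_dps = 2000, mag_gauss = 16)
IMU_NOMINAL_RATE <- 59.5

ACTIVITY_CLASSES <- c("Walking", "Resting", "Tremor", "Dyskinetic", "Other")
POSTURES <- c("standing", "sitting", "lying")

#' Half-up rounding to a fixed number of decimals
#'
#' Base `round()` uses round-half-to-even; report tables in this field
#' conventionally round half away from zero.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Unit conversions between device-native and SI units
#'
#' Signals are carried in device-native units throughout (g for acceleration,
#' deg/s for angular rate, gauss for magnetic field) because every clinical
#' operating point is expressed in them. These helpers convert to SI when
#' needed.
#'
#' @param x numeric vector in the source unit.
#' @return numeric vector in the target unit.
#' @export
gToMs2 <- function(x) x * 9.80665

#' @rdname gToMs2
#' @export
dpsToRads <- function(x) x * pi / 180

zeroCrossingRate <- function(x) {
  # fraction of adjacent sample pairs straddling the (centered) zero line
  if (length(x) < 2) return(0)
  xc <- x - mean(x)
  s <- sign(xc)
  s[s == 0] <- 1
  mean(s[-1] != s[-length(s)])
}

#' One-sided Hann-windowed periodogram
#'
#' Power spectral estimate used for band energies, dominant-frequency and
#' freeze-index computations. The signal mean (DC) is removed; power is
#' normalized so that the sum over returned frequencies equals the variance-like
#' total power of the windowed signal (discrete Parseval).
#'
#' @param x numeric vector (one window of signal).
#' @param fs sampling rate in Hz.
#' @return list with `freq` (Hz, excluding DC) and `power`.
#' @export
periodogramHann <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 4)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  xw <- (x - mean(x)) * w
  sp <- abs(fft(xw))^2 / sum(w^2)
  nh <- floor(n / 2)
  freq <- (1:nh) * fs / n
  power <- sp[2:(nh + 1)]
  # fold the redundant upper half so total power is preserved
  upper <- sp[seq(n, n - nh + 1)]
  if (n %% 2 == 0) upper[nh] <- 0  # Nyquist bin is unique
  power <- power + upper
  list(freq = freq, power = power / n)
}

bandPower <- function(pg, lo, hi) {
  sum(pg$power[pg$freq > lo & pg$freq <= hi])
}

#' Zero-phase Butterworth filtering
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`) so the
#' filtered signal has no phase lag, which matters when event timing (step
#' peaks, tremor onsets) is read off the filtered trace.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges in Hz; use `lo = 0` for a low-pass and
#'   `hi = Inf` for a high-pass.
#' @param order filter order (default 4).
#' @return filtered numeric vector of the same length.
#' @export
butterFilter <- function(x, fs, lo = 0, hi = Inf, order = 4) {
  nyq <- fs / 2
  if (hi >= nyq && lo <= 0) return(x)
  if (lo >= nyq) stop("filter cutoff must be below the Nyquist frequency")
  if (hi < nyq && lo > 0) {
    bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  } else if (hi < nyq) {
    bf <- signal::butter(order, hi / nyq, type = "low")
  } else {
    bf <- signal::butter(order, lo / nyq, type = "high")
  }
  # odd-reflection padding tames the start/end transients of filtfilt
  n <- length(x)
  p <- min(n - 1, round(3 * fs))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1):(p + n)]
}

#' Split a signal into low- and high-frequency components
#'
#' Complementary zero-phase low/high-pass pair about `cutoffHz`; the two
#' components approximately reconstruct the input.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param cutoffHz cutoff frequency, must be below Nyquist.
#' @return list with `low` and `high` components.
#' @export
splitBands <- function(x, fs, cutoffHz) {
  if (cutoffHz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  low <- butterFilter(x, fs, hi = cutoffHz)
  list(low = low, high = x - low)
}

movingAverage <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1) return(x)
  as.numeric(stats::filter(x, rep(1 / n, n), sides = 2, circular = FALSE)) ->
    y
  # fill the edge NAs with the nearest computed value
  idx <- which(!is.na(y))
  if (length(idx) == 0) return(rep(mean(x), length(x)))
  y[seq_len(idx[1] - 1)] <- y[idx[1]]
  y[seq(idx[length(idx)] + 1, length.out = length(x) - idx[length(idx)])] <-
    y[idx[length(idx)]]
  y
}

# pink (1/f) shaping of a white-noise vector via Paul Kellet's IIR
# approximation, rescaled to unit RMS
pinkFilter <- function(w) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  x <- stats::filter(w, b, method = "convolution", sides = 1)
  x[is.na(x)] <- 0
  x <- as.numeric(stats::filter(x, -a[-1], method = "recursive"))
  s <- sd(x)
  if (s == 0) return(x)
  x / s
}

pinkNoise <- function(n) pinkFilter(rnorm(n))

`%||%` <- function(a, b) if (is.null(a)) b else a
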