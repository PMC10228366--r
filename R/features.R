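#' Tri-axial signal energy
#'
#' Energy of a tri-axial window: the sum over samples of the squared values
#' of all three axes, `sum_i sx^2(i) + sy^2(i) + sz^2(i)`. Applied to
#' band-filtered gyroscope windows it yields the low/high-band energies used
#' by the tremor detector; units are (deg/s)^2 x samples for gyroscope input.
#'
#' @param x an n x 3 numeric matrix, or a list of three equal-length vectors.
#' @return non-negative scalar energy.
#' @export
triAxialEnergy <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lens <- lengths(x)
    if (length(x) != 3 || length(unique(lens)) != 1)
      stop("tri-axial input requires three equal-length channels")
    x <- do.call(cbind, x)
  }
  stopifnot(is.matrix(x), ncol(x) == 3)
  sum(x^2)
}

#' Default frequency bins for gyroscope band energies
#'
#' Non-overlapping bins covering (0, Nyquist]: (0-1], (1-3], (3-8], (8-12],
#' (12-Nyquist] Hz. The edges straddle the voluntary-movement band (< 3 Hz),
#' the parkinsonian rest-tremor band (3.5-8 Hz) and the freeze-relevant band.
#'
#' @param fs sampling rate in Hz.
#' @return data.frame with columns `lo`, `hi` (Hz), edges strictly increasing.
#' @export
defaultFrequencyBins <- function(fs = IMU_NOMINAL_RATE) {
  edges <- c(0, 1, 3, 8, 12, fs / 2)
  data.frame(lo = edges[-length(edges)], hi = edges[-1])
}

# Summed per-axis Hann periodogram of a tri-axial signal. Spectra are
# computed per axis and added: the magnitude envelope would rectify an
# oscillation and double its apparent frequency.
triAxialSpectrum <- function(g, fs) {
  pg <- periodogramHann(g[, 1], fs)
  pg$power <- pg$power + periodogramHann(g[, 2], fs)$power +
    periodogramHann(g[, 3], fs)$power
  pg
}

# Hann periodogram of each column of X; returns list(freq, power) with power
# a (floor(n/2) x ncol) matrix. Same math as periodogramHann().
periodogramHannMat <- function(X, fs) {
  n <- nrow(X)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  Xw <- (X - rep(colMeans(X), each = n)) * w
  sp <- abs(stats::mvfft(Xw))^2 / sum(w^2)
  nh <- floor(n / 2)
  power <- sp[2:(nh + 1), , drop = FALSE]
  upper <- sp[seq(n, n - nh + 1), , drop = FALSE]
  if (n %% 2 == 0) upper[nh, ] <- 0
  list(freq = (1:nh) * fs / n, power = (power + upper) / n)
}

#' Time-domain features of one window of a position's stream
#'
#' Per channel: mean, standard deviation, signal energy (sum of squares) and
#' zero-crossing rate of the mean-removed signal; plus one jerk RMS computed
#' from the first differences of the three acceleration channels scaled by
#' the sampling rate (g/s).
#'
#' @param m an n x 9 window matrix (channels `ax..mz`), n >= 2.
#' @param fs sampling rate in Hz.
#' @return named numeric vector of 37 features.
#' @export
timeDomainFeatures <- function(m, fs) {
  stopifnot(nrow(m) >= 2)
  out <- numeric(0)
  for (ch in IMU_CHANNELS) {
    x <- m[, ch]
    out[paste0(ch, "_mean")] <- mean(x)
    out[paste0(ch, "_sd")] <- sd(x)
    out[paste0(ch, "_energy")] <- sum(x^2)
    out[paste0(ch, "_zcr")] <- zeroCrossingRate(x)
  }
  d <- diff(m[, c("ax", "ay", "az")]) * fs
  out["jerk_rms"] <- sqrt(mean(d^2))
  out
}

#' Frequency-domain features: gyroscope band energies
#'
#' Energies of the tri-axial gyroscope signal within the configured
#' frequency bins, from summed per-axis Hann-windowed periodograms (per-axis
#' spectra preserve the oscillation frequency, which the magnitude envelope
#' would double). Because the bins partition (0, Nyquist], the bin energies
#' sum to the total (DC-removed) spectral power.
#'
#' @param g an n x 3 gyroscope window (deg/s), n corresponding to >= 1 s.
#' @param fs sampling rate in Hz.
#' @param bins data.frame from [defaultFrequencyBins()].
#' @return named numeric vector `gyro_band1..gyro_bandK`.
#' @export
frequencyDomainFeatures <- function(g, fs, bins = defaultFrequencyBins(fs)) {
  stopifnot(nrow(g) >= fs)
  pg <- triAxialSpectrum(g, fs)
  e <- vapply(seq_len(nrow(bins)),
              function(i) bandPower(pg, bins$lo[i], bins$hi[i]), numeric(1))
  setNames(e, paste0("gyro_band", seq_len(nrow(bins))))
}

#' The fixed feature schema
#'
#' Names, in fixed order, of the features produced by [buildFeatureTable()]:
#' per position and channel mean/sd/energy/zero-crossing rate (180), one jerk
#' RMS per position (5), pairwise correlations of gyroscope magnitudes
#' between positions (10) and per-position gyroscope band energies (25) —
#' 220 features in total. The roster is a documented reconstruction of the
#' feature families the method draws on (the exact production roster is not
#' public); it is deliberately larger than 140 names.
#'
#' @param bins frequency bins (only the count matters).
#' @return character vector of feature names.
#' @export
featureSchema <- function(bins = defaultFrequencyBins()) {
  nm <- character(0)
  for (pos in IMU_POSITIONS)
    for (ch in IMU_CHANNELS)
      nm <- c(nm, paste0(pos, "_", ch, "_", c("mean", "sd", "energy", "zcr")))
  nm <- c(nm, paste0(IMU_POSITIONS, "_jerk_rms"))
  pairs <- utils::combn(IMU_POSITIONS, 2)
  nm <- c(nm, paste0("cor_", pairs[1, ], "_", pairs[2, ]))
  for (pos in IMU_POSITIONS)
    nm <- c(nm, paste0(pos, "_gyro_band", seq_len(nrow(bins))))
  nm
}

#' Write a feature table as CSV together with a YAML schema manifest
#'
#' The CSV carries one row per window (`window_start_s` + the schema
#' columns); the manifest lists the feature names in order, so downstream
#' consumers can validate column identity.
#'
#' @param ft feature table from [buildFeatureTable()].
#' @param path CSV output path; the manifest is written next to it as
#'   `<path>.schema.yaml`.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(ft, path) {
  write.csv(ft, path, row.names = FALSE)
  yaml::write_yaml(list(n_features = ncol(ft) - 1L,
                        features = setdiff(names(ft), "window_start_s")),
                   paste0(path, ".schema.yaml"))
  invisible(path)
}

#' Build the window-by-feature table for a recording
#'
#' Segments the recording into `windowS`-second windows and computes the full
#' feature schema for each window (see [featureSchema()]). Computation is
#' vectorized across windows; the result is deterministic for a fixed input.
#'
#' @param rec a synchronized [IMURecording-class].
#' @param windowS window length in seconds (default 4).
#' @param bins frequency bins, default [defaultFrequencyBins()].
#' @return data.frame with `window_start_s` followed by the feature columns,
#'   one row per window.
#' @export
buildFeatureTable <- function(rec, windowS = 4, bins = defaultFrequencyBins(samplingRate(rec))) {
  fs <- samplingRate(rec)
  wins <- segmentWindows(rec, windowS)
  nwin <- nrow(wins)
  schema <- featureSchema(bins)
  if (nwin == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(schema) + 1))
    names(out) <- c("window_start_s", schema)
    return(out)
  }
  wlen <- wins$n_samples[1]
  idx <- as.vector(outer(seq_len(wlen) - 1L, wins$start_sample, "+"))
  feat <- list()
  gmag <- list()  # per-position gyro magnitude matrices for correlations
  for (pos in IMU_POSITIONS) {
    m <- imuStream(rec, pos)
    chan <- list()
    for (ch in IMU_CHANNELS) {
      X <- matrix(m[idx, ch], wlen, nwin)
      chan[[ch]] <- X
      mu <- colMeans(X)
      ss <- colSums(X^2)
      feat[[paste0(pos, "_", ch, "_mean")]] <- mu
      feat[[paste0(pos, "_", ch, "_sd")]] <- sqrt(pmax(0, (ss - wlen * mu^2) / (wlen - 1)))
      feat[[paste0(pos, "_", ch, "_energy")]] <- ss
      Xc <- X - rep(mu, each = wlen)
      S <- sign(Xc); S[S == 0] <- 1
      feat[[paste0(pos, "_", ch, "_zcr")]] <- colMeans(S[-1, , drop = FALSE] != S[-wlen, , drop = FALSE])
    }
    D2 <- 0
    for (ch in c("ax", "ay", "az")) {
      D <- (chan[[ch]][-1, , drop = FALSE] - chan[[ch]][-wlen, , drop = FALSE]) * fs
      D2 <- D2 + colSums(D^2)
    }
    feat[[paste0(pos, "_jerk_rms")]] <- sqrt(D2 / (3 * (wlen - 1)))
    G <- sqrt(chan$gx^2 + chan$gy^2 + chan$gz^2)
    gmag[[pos]] <- G
    pgm <- periodogramHannMat(chan$gx, fs)
    pgm$power <- pgm$power + periodogramHannMat(chan$gy, fs)$power +
      periodogramHannMat(chan$gz, fs)$power
    bidx <- vapply(pgm$freq, function(f) which(f > bins$lo & f <= bins$hi + 1e-12)[1], integer(1))
    be <- rowsum(pgm$power, bidx)
    for (i in seq_len(nrow(bins)))
      feat[[paste0(pos, "_gyro_band", i)]] <-
        if (as.character(i) %in% rownames(be)) be[as.character(i), ] else rep(0, nwin)
  }
  pairs <- utils::combn(IMU_POSITIONS, 2)
  for (k in seq_len(ncol(pairs))) {
    A <- gmag[[pairs[1, k]]]; B <- gmag[[pairs[2, k]]]
    muA <- colMeans(A); muB <- colMeans(B)
    sA <- colSums(A^2) - wlen * muA^2
    sB <- colSums(B^2) - wlen * muB^2
    sAB <- colSums(A * B) - wlen * muA * muB
    r <- ifelse(sA > 1e-24 & sB > 1e-24, sAB / sqrt(pmax(sA * sB, 1e-300)), 0)
    feat[[paste0("cor_", pairs[1, k], "_", pairs[2, k])]] <- pmin(1, pmax(-1, r))
  }
  out <- data.frame(window_start_s = wins$start_s, feat[schema], check.names = FALSE)
  stopifnot(all(is.finite(as.matrix(out))))
  out
}
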