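# Dyskinesia from 5-minute non-walking regions; bradykinesia from the
# fraction of slow discrete movements per 30-minute bin.

#' Per-window 1-4 Hz band RMS of each limb's gyroscope
#'
#' Dyskinetic movement is band-limited, irregular angular motion in the
#' 1-4 Hz range on multiple limbs. Each limb's gyroscope axes are
#' zero-phase band-passed over the full stream, then the tri-axial RMS is
#' taken per analysis window.
#'
#' @param rec an [IMURecording-class].
#' @param windows window table from [segmentWindows()].
#' @param band two-element band in Hz (default `c(1, 4)`).
#' @return matrix windows x 4 limbs of band RMS (deg/s).
#' @export
dyskBandRms <- function(rec, windows, band = c(1, 4)) {
  fs <- samplingRate(rec)
  out <- matrix(0, nrow(windows), length(LIMBS), dimnames = list(NULL, LIMBS))
  wlen <- windows$n_samples[1]
  idx <- as.vector(outer(seq_len(wlen) - 1L, windows$start_sample, "+"))
  for (limb in LIMBS) {
    g <- imuStream(rec, limb)[, 4:6]
    gb <- apply(g, 2, butterFilter, fs = fs, lo = band[1], hi = band[2])
    sq <- rowSums(gb^2)
    out[, limb] <- sqrt(colMeans(matrix(sq[idx], wlen, nrow(windows))))
  }
  out
}

#' Find dyskinetic 5-minute regions
#'
#' The recording is divided into 5-minute intervals aligned to the recording
#' start. Walking windows are excluded from each interval (dyskinesia is
#' assessed while not walking); an interval that is entirely walking is
#' excluded from scoring. A region is flagged dyskinetic when the mean
#' Dyskinetic posterior over the remaining windows exceeds `gate`; its
#' severity is the mean multi-limb 1-4 Hz band RMS scaled to the device
#' scale (`scale`, calibrated so a moderate dyskinesia sits near the 1.66
#' operating point).
#'
#' @param rec an [IMURecording-class].
#' @param windows window table (with `bin`).
#' @param labels per-window activity labels.
#' @param pDysk per-window Dyskinetic posterior.
#' @param intervalMinutes region length (default 5).
#' @param gate posterior gate (default 0.5).
#' @param scale deg/s-to-device-scale factor; default from the shipped
#'   calibration.
#' @param rms optional precomputed [dyskBandRms()] matrix (skips the
#'   filtering pass).
#' @return data.frame per interval: `interval, start_s, excluded,
#'   dyskinetic, p_dysk, band_rms, severity`.
#' @export
detectDyskineticRegions <- function(rec, windows, labels, pDysk,
                                    intervalMinutes = 5, gate = 0.5,
                                    scale = NULL, rms = NULL) {
  if (is.null(scale)) scale <- defaultCalibration()$dysk_scale
  iv <- floor(windows$start_s / (intervalMinutes * 60)) + 1L
  if (is.null(rms)) rms <- dyskBandRms(rec, windows)
  limbMean <- rowMeans(rms)
  out <- lapply(sort(unique(iv)), function(k) {
    sel <- which(iv == k)
    nw <- sel[as.character(labels[sel]) != "Walking"]
    if (length(nw) == 0)
      return(data.frame(interval = k, start_s = (k - 1) * intervalMinutes * 60,
                        excluded = TRUE, dyskinetic = FALSE, p_dysk = NA_real_,
                        band_rms = NA_real_, severity = NA_real_))
    p <- mean(pDysk[nw])
    br <- mean(limbMean[nw])
    dysk <- p > gate
    data.frame(interval = k, start_s = (k - 1) * intervalMinutes * 60,
               excluded = FALSE, dyskinetic = dysk, p_dysk = p,
               band_rms = br, severity = if (dysk) scale * br else 0)
  })
  do.call(rbind, out)
}

#' 30-minute dyskinesia score
#'
#' Mean severity over the scored (non-excluded) 5-minute regions of a bin;
#' `NA` when every region in the bin was excluded.
#'
#' @param regions data.frame from [detectDyskineticRegions()].
#' @param binMinutes bin length (default 30).
#' @return data.frame `bin`, `dyskinesia_score`.
#' @export
dyskinesiaScore30 <- function(regions, binMinutes = 30) {
  bin <- floor(regions$start_s / (binMinutes * 60)) + 1L
  out <- lapply(sort(unique(bin)), function(b) {
    r <- regions[bin == b & !regions$excluded, ]
    data.frame(bin = b, dyskinesia_score = if (nrow(r)) mean(r$severity) else NA_real_)
  })
  do.call(rbind, out)
}

#' Segment discrete movements from a wrist gyroscope stream
#'
#' Movement events are supra-threshold bursts of the smoothed gyroscope
#' magnitude with hysteresis: an event opens when the envelope exceeds
#' `onDps` and closes when it falls below `offDps`. Events shorter than
#' `minDurS` or longer than `maxDurS` are discarded, as are events not fully
#' inside spans labeled Resting or Other (voluntary movement capacity is
#' only assessable outside walking/tremor/dyskinesia).
#'
#' @param g n x 3 wrist gyroscope stream (deg/s).
#' @param fs sampling rate (Hz).
#' @param eligible logical per-sample mask (TRUE where assessment is
#'   allowed); default all samples.
#' @param onDps,offDps hysteresis thresholds (deg/s), default 40/20.
#' @param minDurS,maxDurS event duration bounds in seconds.
#' @param smoothS smoothing window for the envelope (s).
#' @return data.frame `start_sample, end_sample, dur_s, peak_dps`.
#' @export
segmentMovements <- function(g, fs, eligible = NULL, onDps = 40, offDps = 20,
                             minDurS = 0.2, maxDurS = 5, smoothS = 0.25) {
  magRaw <- sqrt(rowSums(g^2))
  mag <- movingAverage(magRaw, round(smoothS * fs))
  n <- length(mag)
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  above <- mag > offDps
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values)) {
    s <- starts[i]; e <- ends[i]
    if (max(mag[s:e]) < onDps) next      # never reached the ON threshold
    dur <- (e - s + 1) / fs
    if (dur < minDurS || dur > maxDurS) next
    if (!all(eligible[s:e])) next
    # peak speed read off the raw magnitude (the smoothed envelope would
    # systematically shave short pulses)
    out[[length(out) + 1]] <- data.frame(
      start_sample = s, end_sample = e, dur_s = dur, peak_dps = max(magRaw[s:e]))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_sample = integer(), end_sample = integer(),
               dur_s = numeric(), peak_dps = numeric())
}

#' Normative movement-speed threshold from control events
#'
#' The bradykinetic cut is the 5th percentile of the control group's
#' peak-speed distribution: movements slower than (nearly all of) what
#' controls produce are counted as bradykinetic.
#'
#' @param peaks numeric vector of control event peak speeds (deg/s),
#'   >= `minEvents` values.
#' @param prob percentile (default 0.05).
#' @param minEvents minimum event count (default 100).
#' @return threshold in deg/s.
#' @export
fitNormative <- function(peaks, prob = 0.05, minEvents = 100) {
  if (length(peaks) < minEvents)
    stop("need at least ", minEvents, " control events to fit a norm")
  unname(quantile(peaks, prob))
}

#' 30-minute bradykinesia score
#'
#' Percentage of detected movements in the bin whose peak speed is below
#' the control-derived norm; `NA` (no data) when the bin has no movements.
#'
#' @param peaks event peak speeds in the bin (deg/s).
#' @param normative threshold from [fitNormative()].
#' @return percentage in \[0, 100\] or `NA`.
#' @export
bradykinesiaScore <- function(peaks, normative) {
  if (length(peaks) == 0) return(NA_real_)
  100 * mean(peaks < normative)
}
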