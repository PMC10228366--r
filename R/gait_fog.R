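# Gait: walking-region merging, TC/RS/IC step detection on the shank
# medio-lateral angular velocity, gait features, linear gait-impairment
# score; freezing of gait via the freeze index on pre-walk pauses.

#' Merge consecutive Walking windows into walking regions
#'
#' Runs of Walking-labeled windows are merged; gaps of at most
#' `bridgeWindows` non-Walking windows between runs are bridged; regions
#' shorter than `minRegionS` seconds are discarded. Merging improves the
#' statistical estimation of gait parameters over single 4-s windows.
#'
#' @param labels per-window activity labels (ordered).
#' @param windowS window length in seconds.
#' @param bridgeWindows maximum gap (in windows) to bridge (default 1).
#' @param minRegionS minimum region duration in seconds (default 8).
#' @return data.frame: `startWin`, `endWin` (inclusive window indices),
#'   `start_s`, `end_s` (half-open).
#' @export
mergeWalking <- function(labels, windowS = 4, bridgeWindows = 1, minRegionS = 8) {
  w <- as.character(labels) == "Walking"
  if (!any(w)) return(data.frame(startWin = integer(), endWin = integer(),
                                 start_s = numeric(), end_s = numeric()))
  r <- rle(w)
  # bridge short non-walking gaps flanked by walking
  if (length(r$lengths) > 2) {
    for (i in 2:(length(r$lengths) - 1)) {
      if (!r$values[i] && r$lengths[i] <= bridgeWindows &&
          r$values[i - 1] && r$values[i + 1])
        r$values[i] <- TRUE
    }
  }
  w <- inverse.rle(r)
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * windowS >= minRegionS
  data.frame(startWin = starts[keep], endWin = ends[keep],
             start_s = (starts[keep] - 1) * windowS,
             end_s = ends[keep] * windowS)
}

#' Detect steps from shank medio-lateral angular velocity
#'
#' Within a walking region, the 6-Hz low-passed signal shows one large
#' positive lobe per gait cycle at maximum rotational speed (RS, mid-swing)
#' flanked by negative peaks at terminal contact (TC, heel off) before and
#' initial contact (IC, heel strike) after. RS peaks are located first;
#' each is paired with the minimum in a window before (TC) and after (IC).
#' Steps violating TC < RS < IC or overlapping the previous step are
#' dropped.
#'
#' @param gz shank medio-lateral (sagittal-plane) angular velocity, deg/s.
#' @param fs sampling rate (Hz).
#' @param minPeakDps minimum RS peak height (adaptive floor), deg/s.
#' @return data.frame `tc, rs, ic` (1-based sample indices); zero rows when
#'   fewer than two cycles are detectable.
#' @export
detectSteps <- function(gz, fs, minPeakDps = 30) {
  y <- butterFilter(gz, fs, hi = 6)
  thr <- max(minPeakDps, 0.3 * quantile(y, 0.98))
  pk <- pracma::findpeaks(y, minpeakheight = thr,
                          minpeakdistance = round(0.5 * fs))
  if (is.null(pk) || nrow(pk) < 2)
    return(data.frame(tc = integer(), rs = integer(), ic = integer()))
  rs <- sort(pk[, 2])
  half <- round(0.45 * fs)
  steps <- lapply(rs, function(r) {
    lo <- max(1, r - half); hi <- min(length(y), r + half)
    pre <- y[lo:(r - 1)]; post <- y[(r + 1):hi]
    tc <- lo + which.min(pre) - 1L
    ic <- r + which.min(post)
    if (y[tc] < 0 && y[ic] < 0 && tc < r && r < ic)
      data.frame(tc = tc, rs = r, ic = ic) else NULL
  })
  st <- do.call(rbind, steps)
  if (is.null(st) || nrow(st) < 2)
    return(data.frame(tc = integer(), rs = integer(), ic = integer()))
  keep <- c(TRUE, st$tc[-1] >= st$ic[-nrow(st)])
  st[keep, , drop = FALSE]
}

#' Gait features of one walking region
#'
#' RoM: per-cycle range of the shank sagittal angle, obtained by integrating
#' the medio-lateral angular velocity between consecutive TC events with
#' per-cycle linear drift removal. Cadence: steps/min for both feet, i.e.
#' twice the stride rate seen by one shank. Swing time: TC-to-IC interval.
#' Variability: coefficient of variation of swing times.
#'
#' @param steps data.frame from [detectSteps()] (>= 2 rows).
#' @param gz the same angular-velocity signal the steps were detected on.
#' @param fs sampling rate (Hz).
#' @return list `rom_deg, cadence, swing_s, swing_cv, n_steps`, or `NULL`
#'   when fewer than 2 steps are available.
#' @export
computeGaitFeatures <- function(steps, gz, fs) {
  if (is.null(steps) || nrow(steps) < 2) return(NULL)
  y <- butterFilter(gz, fs, hi = 6)
  roms <- numeric(0)
  for (i in seq_len(nrow(steps) - 1)) {
    seg <- y[steps$tc[i]:steps$tc[i + 1]]
    ang <- cumsum(seg) / fs
    t <- seq_along(ang)
    fitl <- lm.fit(cbind(1, t), ang)
    roms <- c(roms, diff(range(fitl$residuals)))
  }
  strideT <- median(diff(steps$tc)) / fs
  swing <- (steps$ic - steps$tc) / fs
  list(rom_deg = mean(roms), cadence = 120 / strideT,
       swing_s = mean(swing),
       swing_cv = if (mean(swing) > 0) sd(swing) / mean(swing) else 0,
       n_steps = nrow(steps))
}

#' Linear gait-impairment score (UPDRS item 29 scale)
#'
#' Affine combination of standardized gait features clipped to \[0, 4\].
#' The shank range of motion dominates: its coefficient is negative (less
#' rotation, higher impairment) and the largest in magnitude, so the score
#' is strictly decreasing in RoM with the other features held fixed.
#'
#' @param features list/data.frame with `rom_deg`, `cadence`, `swing_cv`.
#' @param model coefficient set: list with `intercept`, `coef` (named),
#'   `center`, `scale`; default the calibration shipped with the package.
#' @return score in \[0, 4\].
#' @export
gaitScore <- function(features, model = defaultGaitModel()) {
  nm <- names(model$coef)
  x <- unlist(features[nm])
  z <- (x - unlist(model$center[nm])) / unlist(model$scale[nm])
  min(4, max(0, model$intercept + sum(unlist(model$coef) * z)))
}

#' Fit the gait-score linear model on labeled data
#'
#' Least-squares fit of severity on standardized (`rom_deg`, `cadence`,
#' `swing_cv`). Fitted on the synthetic cohort's feature/severity pairs to
#' produce the shipped default coefficients.
#'
#' @param df data.frame with `rom_deg`, `cadence`, `swing_cv`, `severity`.
#' @return a gait model list (see [gaitScore()]).
#' @export
fitGaitModel <- function(df) {
  nm <- c("rom_deg", "cadence", "swing_cv")
  center <- lapply(df[nm], mean)
  scale <- lapply(df[nm], function(x) max(sd(x), 1e-9))
  Z <- scale(as.matrix(df[nm]), center = unlist(center), scale = unlist(scale))
  fit <- lm.fit(cbind(1, Z), df$severity)
  cf <- fit$coefficients
  if (cf[2] >= 0)
    warning("expected a negative RoM coefficient; calibration data look degenerate")
  list(intercept = unname(cf[1]), coef = setNames(as.list(unname(cf[-1])), nm),
       center = center, scale = scale)
}

defaultGaitModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- yaml::read_yaml(system.file("extdata", "calibration.yaml",
                                            package = "pdmotor", mustWork = TRUE))$gait_model
    cache
  }
})

#' Freeze index of a shank gyroscope segment
#'
#' Ratio of freeze-band (3-8 Hz) to locomotor-band (0.5-3 Hz) power of the
#' summed per-axis gyroscope periodogram. The denominator is floored at 1e-6 of
#' the total power so quiet segments yield a finite (zero-power gives 0)
#' index rather than dividing by zero.
#'
#' @param g n x 3 shank gyroscope segment (>= 2 s), deg/s.
#' @param fs sampling rate (Hz).
#' @return list `fi`, `freezePower`, `locoPower`.
#' @export
freezeIndex <- function(g, fs) {
  stopifnot(nrow(g) >= 2 * fs)
  pg <- triAxialSpectrum(g, fs)
  pf <- bandPower(pg, 3, 8)
  pl <- bandPower(pg, 0.5, 3)
  tot <- sum(pg$power)
  if (tot <= 0) return(list(fi = 0, freezePower = 0, locoPower = 0))
  list(fi = pf / max(pl, 1e-6 * tot), freezePower = pf, locoPower = pl)
}

#' Detect freezing-of-gait events before walking initiation
#'
#' Candidate regions are pauses of 2-10 s immediately preceding the start of
#' a walking region. An event is declared when the freeze index exceeds
#' `fiThreshold` on both shanks, trembling power is actually present on both
#' (freeze-band RMS above `minTrembleDps`), and the pause windows are not
#' labeled Tremor or Dyskinetic (discrimination against those activities).
#' The session FoG score is the ratio of events to candidate regions; the
#' same ratio is reported per 30-minute bin.
#'
#' @param rec an [IMURecording-class].
#' @param windows window table (with `bin`) from
#'   [segmentWindows()] + [assignBins()].
#' @param labels per-window activity labels.
#' @param fiThreshold freeze-index threshold (default 2).
#' @param minTrembleDps minimum freeze-band RMS on each shank, deg/s.
#' @param windowS window length in seconds.
#' @return list `events` (start_s, dur_s), `ratio` (session; `NA` when no
#'   candidates), `bins` (per-bin candidates/events/ratio).
#' @export
detectFog <- function(rec, windows, labels, fiThreshold = 2,
                      minTrembleDps = 5, windowS = 4) {
  detectFogCore(imuStream(rec, "left_ankle")[, 4:6],
                imuStream(rec, "right_ankle")[, 4:6],
                samplingRate(rec), windows, labels, fiThreshold,
                minTrembleDps, windowS)
}

detectFogCore <- function(gl, gr, fs, windows, labels, fiThreshold = 2,
                          minTrembleDps = 5, windowS = 4) {
  regions <- mergeWalking(labels, windowS)
  events <- list(); cand <- list()
  for (i in seq_len(nrow(regions))) {
    sw <- regions$startWin[i]
    if (sw < 2) next
    # pause: up to two non-walking windows (8 s) immediately before the start
    pw <- sw - 1L
    if (as.character(labels[pw]) == "Walking") next
    p0 <- pw
    if (pw > 1 && as.character(labels[pw - 1]) != "Walking") p0 <- pw - 1L
    i0 <- windows$start_sample[p0]
    i1 <- windows$start_sample[pw] + windows$n_samples[pw] - 1L
    if ((i1 - i0 + 1) / fs < 2) next
    lab <- as.character(labels[p0:pw])
    seg <- i0:i1
    fiL <- freezeIndex(gl[seg, , drop = FALSE], fs)
    fiR <- freezeIndex(gr[seg, , drop = FALSE], fs)
    isEvent <- !any(lab %in% c("Tremor", "Dyskinetic")) &&
      fiL$fi > fiThreshold && fiR$fi > fiThreshold &&
      sqrt(fiL$freezePower) > minTrembleDps && sqrt(fiR$freezePower) > minTrembleDps
    cand[[length(cand) + 1]] <- data.frame(
      start_s = windows$start_s[p0], bin = windows$bin[p0], event = isEvent)
    if (isEvent)
      events[[length(events) + 1]] <- data.frame(
        start_s = windows$start_s[p0], dur_s = (i1 - i0 + 1) / fs)
  }
  candDf <- if (length(cand)) do.call(rbind, cand) else
    data.frame(start_s = numeric(), bin = integer(), event = logical())
  byBin <- if (nrow(candDf)) {
    agg <- aggregate(event ~ bin, candDf, function(e) c(n = length(e), k = sum(e)))
    data.frame(bin = agg$bin, candidates = agg$event[, "n"],
               events = agg$event[, "k"],
               ratio = agg$event[, "k"] / agg$event[, "n"])
  } else data.frame(bin = integer(), candidates = integer(),
                    events = integer(), ratio = numeric())
  list(events = if (length(events)) do.call(rbind, events) else
         data.frame(start_s = numeric(), dur_s = numeric()),
       ratio = if (nrow(candDf)) mean(candDf$event) else NA_real_,
       bins = byBin)
}
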