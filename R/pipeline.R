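# End-to-end orchestration: from a synchronized recording plus per-window
# activity labels/posteriors to the per-30-minute symptom table, and the
# multi-day report.

#' Default run configuration
#'
#' All tunable parameters with their defaults, including the clinical
#' operating thresholds on each device measure (arm bradykinesia 0.7 as a
#' fraction of movements, gait 1.6, wrist tremor 1.64, leg tremor posterior
#' 0.16, dyskinesia 1.66, OFF probability 0.5, FoG ratio 0.02).
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() {
  list(
    windowS = 4, tremorWindowS = 3, binMinutes = 30, intervalMinutes = 5,
    thresholds = list(brady = 0.7, gait = 1.6, wrist_tremor = 1.64,
                      leg_tremor = 0.16, dyskinesia = 1.66, off = 0.5,
                      fog = 0.02),
    fiThreshold = 2, minConstancy = 0.25, dyskGate = 0.35,
    movementOnDps = 40, movementOffDps = 20,
    movementDurS = c(0.2, 5), normativePercentile = 0.05,
    movementFloorDps2 = 25, offTimeThreshold = 0.55
  )
}

#' Read a configuration YAML, merged over the defaults
#'
#' @param path YAML file; keys override [defaultConfig()] entries.
#' @return configuration list.
#' @export
readConfig <- function(path) {
  cfg <- defaultConfig()
  usr <- yaml::read_yaml(path)
  merge2 <- function(base, over) {
    for (k in names(over))
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge2(base[[k]], over[[k]]) else over[[k]]
    base
  }
  merge2(cfg, usr)
}

defaultCalibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- yaml::read_yaml(system.file("extdata", "calibration.yaml",
                                            package = "pdmotor", mustWork = TRUE))
    cache
  }
})

# vectorized per-3-s-window tremor series for one position
tremorSeries <- function(rec, position, wins3, tree) {
  fs <- samplingRate(rec)
  g <- imuStream(rec, position)[, 4:6]
  band <- apply(g, 2, butterFilter, fs = fs, lo = TREMOR_BAND[1], hi = TREMOR_BAND[2])
  low <- apply(g, 2, butterFilter, fs = fs, hi = VOLUNTARY_CUTOFF)
  wlen <- wins3$n_samples[1]
  idx <- as.vector(outer(seq_len(wlen) - 1L, wins3$start_sample, "+"))
  nwin <- nrow(wins3)
  sqBand <- matrix(rowSums(band^2)[idx], wlen, nwin)
  sqLow <- matrix(rowSums(low^2)[idx], wlen, nwin)
  te <- colSums(sqBand); le <- colSums(sqLow)
  pgm <- periodogramHannMat(matrix(g[idx, 1], wlen, nwin), fs)
  pgm$power <- pgm$power + periodogramHannMat(matrix(g[idx, 2], wlen, nwin), fs)$power +
    periodogramHannMat(matrix(g[idx, 3], wlen, nwin), fs)$power
  inb <- pgm$freq >= TREMOR_BAND[1] & pgm$freq <= TREMOR_BAND[2]
  bp <- pgm$power[inb, , drop = FALSE]
  dom <- pgm$freq[inb][apply(bp, 2, which.max)]
  cmean <- colMeans(bp)
  sharp <- ifelse(cmean > 0, apply(bp, 2, max) / cmean, 0)
  feats <- data.frame(low_energy = le, tremor_energy = te,
                      ratio = te / pmax(le, 1e-9), dom_freq = dom,
                      peak_sharpness = sharp)
  data.frame(window = wins3$window, start_s = wins3$start_s,
             present = predictTremorTree(tree, feats) == "tremor",
             dominant_freq = dom,
             amplitude = sqrt(colMeans(sqBand)))
}

#' Label-free symptom inputs for one recording
#'
#' Everything the symptom estimators need that does not depend on activity
#' labels: per-limb 3-s tremor series, per-window 1-4 Hz dyskinesia band
#' RMS, candidate wrist movement events (unmasked), per-window movement
#' power, and the ankle gyroscope streams (kept for step detection and the
#' freeze index). Computing these alongside feature extraction lets a whole
#' cohort be simulated and processed in a single pass.
#'
#' @param rec a synchronized [IMURecording-class].
#' @param config configuration list.
#' @param tremorTree tremor decision tree.
#' @return a `symptomInputs` list.
#' @export
symptomInputs <- function(rec, config = defaultConfig(),
                          tremorTree = defaultTremorTree()) {
  fs <- samplingRate(rec)
  wins <- assignBins(segmentWindows(rec, config$windowS), config$binMinutes)
  wins3 <- segmentWindows(rec, config$tremorWindowS)
  tremor <- lapply(setNames(nm = c("left_wrist", "right_wrist",
                                   "left_ankle", "right_ankle")),
                   function(pos) tremorSeries(rec, pos, wins3, tremorTree))
  movements <- lapply(setNames(nm = c("left_wrist", "right_wrist")),
                      function(pos)
    segmentMovements(imuStream(rec, pos)[, 4:6], fs,
                     onDps = config$movementOnDps,
                     offDps = config$movementOffDps,
                     minDurS = config$movementDurS[1],
                     maxDurS = config$movementDurS[2]))
  wlen <- wins$n_samples[1]
  idx <- as.vector(outer(seq_len(wlen) - 1L, wins$start_sample, "+"))
  pow <- 0
  for (pos in IMU_POSITIONS) {
    sq <- rowSums(imuStream(rec, pos)[, 4:6]^2)
    pow <- pow + colMeans(matrix(sq[idx], wlen, nrow(wins))) / 5
  }
  list(fs = fs, nSamples = length(rec), windows = wins, wins3 = wins3,
       tremor = tremor, dyskRms = dyskBandRms(rec, wins),
       movements = movements, power = pow,
       ankleGyro = list(left_ankle = imuStream(rec, "left_ankle")[, 4:6],
                        right_ankle = imuStream(rec, "right_ankle")[, 4:6]))
}

#' Compute the per-30-minute symptom table
#'
#' Runs every symptom estimator given per-window activity labels and class
#' posteriors (typically out-of-sample predictions from [evaluateLoso()] or
#' [predictActivity()]): wrist tremor per wrist and the analogous spectral
#' score per ankle (3-s windows, gated to Resting/Other activity), the mean
#' Tremor posterior, gait features and score from merged walking regions
#' (plus a variant excluding dyskinetic 5-minute intervals), the dyskinesia
#' score, the bradykinesia percentage per wrist against the control-derived
#' norm, the FoG event/candidate ratio, and the activity summaries (lack of
#' movement, activity level, resting time).
#'
#' @param rec a synchronized [IMURecording-class], or a precomputed
#'   [symptomInputs()] list.
#' @param labels per-4-s-window activity labels (length = window count).
#' @param posterior matrix of per-window class posteriors (columns named by
#'   class; missing classes are treated as probability 0).
#' @param config configuration list ([defaultConfig()]).
#' @param tremorTree tremor decision tree (default shipped tree).
#' @param gaitModel gait-score coefficients (default shipped calibration).
#' @param normative bradykinesia speed norm in deg/s (default shipped
#'   calibration).
#' @return list: `bins` (per-bin symptom data.frame), `fog`, `dyskRegions`,
#'   `movements`, `gaitRegions`.
#' @export
detectSymptoms <- function(rec, labels, posterior, config = defaultConfig(),
                           tremorTree = defaultTremorTree(),
                           gaitModel = defaultGaitModel(),
                           normative = NULL) {
  inp <- if (is(rec, "IMURecording"))
    symptomInputs(rec, config, tremorTree) else rec
  if (is.null(normative)) normative <- defaultCalibration()$brady_normative_dps
  fs <- inp$fs
  wins <- inp$windows
  stopifnot(length(labels) == nrow(wins))
  labels <- as.character(labels)
  getPost <- function(cls) {
    if (!is.null(colnames(posterior)) && cls %in% colnames(posterior))
      posterior[, cls] else rep(0, nrow(wins))
  }
  bins <- sort(unique(wins$bin))
  out <- data.frame(bin = bins,
                    bin_start_s = (bins - 1) * config$binMinutes * 60)
  restOther <- labels %in% c("Resting", "Other")

  ## wrist + ankle tremor: 3-s windows gated to rest-like activity
  ## (Resting/Other per the assessment rule, plus the Tremor class itself,
  ## which is rest with tremor present - excluding it would discard the
  ## very windows being scored)
  host4 <- pmin(floor(inp$wins3$start_s / config$windowS) + 1L, nrow(wins))
  eligible3 <- (restOther | labels == "Tremor")[host4]
  bin3 <- floor(inp$wins3$start_s / (config$binMinutes * 60)) + 1L
  tremCols <- c(left_wrist = "tremor_lw", right_wrist = "tremor_rw",
                left_ankle = "tremor_ll", right_ankle = "tremor_rl")
  for (pos in names(tremCols)) {
    ts <- inp$tremor[[pos]]
    sc <- vapply(bins, function(b) {
      det <- ts[eligible3 & bin3 == b, ]
      unlist(wristTremor30(det, minConstancy = config$minConstancy))
    }, numeric(2))
    out[[tremCols[pos]]] <- sc[1, ]
    out[[paste0("constancy_", sub("tremor_", "", tremCols[pos]))]] <- sc[2, ]
  }
  pT <- getPost("Tremor")
  out$leg_tremor_posterior <- vapply(bins, function(b)
    legTremor30(pT[wins$bin == b]), numeric(1))

  ## dyskinesia
  dyskRegions <- detectDyskineticRegions(NULL, wins, labels, getPost("Dyskinetic"),
                                         config$intervalMinutes, config$dyskGate,
                                         rms = inp$dyskRms)
  ds <- dyskinesiaScore30(dyskRegions, config$binMinutes)
  out$dyskinesia_score <- ds$dyskinesia_score[match(bins, ds$bin)]

  ## gait
  regions <- mergeWalking(labels, config$windowS)
  dyskIv <- dyskRegions$interval[!dyskRegions$excluded & dyskRegions$dyskinetic]
  gaitRows <- list()
  for (i in seq_len(nrow(regions))) {
    i0 <- wins$start_sample[regions$startWin[i]]
    i1 <- wins$start_sample[regions$endWin[i]] + wins$n_samples[regions$endWin[i]] - 1L
    fts <- list()
    for (side in c("left_ankle", "right_ankle")) {
      gz <- inp$ankleGyro[[side]][i0:i1, 3]
      st <- detectSteps(gz, fs)
      f <- computeGaitFeatures(st, gz, fs)
      if (!is.null(f)) fts[[side]] <- f
    }
    if (length(fts) == 0) next
    agg <- lapply(c("rom_deg", "cadence", "swing_s", "swing_cv"), function(nm)
      mean(vapply(fts, function(f) f[[nm]], numeric(1))))
    names(agg) <- c("rom_deg", "cadence", "swing_s", "swing_cv")
    agg$n_steps <- sum(vapply(fts, function(f) f$n_steps, numeric(1)))
    gaitRows[[length(gaitRows) + 1]] <- data.frame(
      start_s = regions$start_s[i], bin = wins$bin[regions$startWin[i]],
      interval = floor(regions$start_s[i] / (config$intervalMinutes * 60)) + 1L,
      rom_deg = agg$rom_deg, cadence = agg$cadence, swing_s = agg$swing_s,
      swing_cv = agg$swing_cv, n_steps = agg$n_steps,
      score = gaitScore(agg, gaitModel))
  }
  gaitDf <- if (length(gaitRows)) do.call(rbind, gaitRows) else NULL
  gaitAgg <- function(b, excludeDysk = FALSE) {
    if (is.null(gaitDf)) return(c(NA, NA, NA, 0))
    gd <- gaitDf[gaitDf$bin == b, ]
    if (excludeDysk) gd <- gd[!(gd$interval %in% dyskIv), ]
    if (nrow(gd) == 0) return(c(NA, NA, NA, 0))
    w <- gd$n_steps / sum(gd$n_steps)
    c(sum(w * gd$score), sum(w * gd$rom_deg), sum(w * gd$cadence), sum(gd$n_steps))
  }
  ga <- vapply(bins, gaitAgg, numeric(4))
  gan <- vapply(bins, gaitAgg, numeric(4), excludeDysk = TRUE)
  out$gait_score <- ga[1, ]; out$rom_deg <- ga[2, ]
  out$cadence <- ga[3, ]; out$steps_count <- ga[4, ]
  out$gait_score_nodysk <- gan[1, ]

  ## bradykinesia: movement events fully inside Resting/Other windows
  movements <- list()
  for (pos in c("left_wrist", "right_wrist")) {
    ev <- inp$movements[[pos]]
    if (nrow(ev)) {
      w0 <- pmin(floor((ev$start_sample - 1) / wins$n_samples[1]) + 1L, nrow(wins))
      w1 <- pmin(floor((ev$end_sample - 1) / wins$n_samples[1]) + 1L, nrow(wins))
      ok <- vapply(seq_len(nrow(ev)), function(i)
        all(restOther[w0[i]:w1[i]]), logical(1))
      ev <- ev[ok, , drop = FALSE]
    }
    ev$bin <- if (nrow(ev)) floor((ev$start_sample - 1) / fs / (config$binMinutes * 60)) + 1L else integer(0)
    ev$limb <- if (nrow(ev)) pos else character(0)
    movements[[pos]] <- ev
    suffix <- if (pos == "left_wrist") "lw" else "rw"
    out[[paste0("brady_", suffix)]] <- vapply(bins, function(b)
      bradykinesiaScore(ev$peak_dps[ev$bin == b], normative), numeric(1))
    out[[paste0("movements_count_", suffix)]] <- vapply(bins, function(b)
      sum(ev$bin == b), numeric(1))
  }

  ## freezing of gait
  fog <- detectFogCore(inp$ankleGyro$left_ankle, inp$ankleGyro$right_ankle,
                       fs, wins, labels, config$fiThreshold,
                       windowS = config$windowS)
  out$fog_ratio <- fog$bins$ratio[match(bins, fog$bins$bin)]

  ## activity summaries
  out$lack_of_movement <- vapply(bins, function(b)
    mean(inp$power[wins$bin == b] < config$movementFloorDps2), numeric(1))
  out$activity_level <- vapply(bins, function(b)
    mean(inp$power[wins$bin == b]), numeric(1))
  out$resting_time <- vapply(bins, function(b)
    mean(labels[wins$bin == b] == "Resting"), numeric(1))
  out$n_windows <- vapply(bins, function(b) sum(wins$bin == b), numeric(1))
  list(bins = out, fog = fog, dyskRegions = dyskRegions,
       movements = do.call(rbind, movements), gaitRegions = gaitDf)
}

#' Per-bin symptom table for a whole simulated cohort
#'
#' Regenerates each subject-day (deterministically) and runs
#' [detectSymptoms()] with the supplied out-of-sample labels/posteriors from
#' a leave-one-subject-out evaluation, attaching subject, day, diary state
#' and the true severities.
#'
#' @param plan a `cohortPlan` from [simulateCohort()].
#' @param featureRows data.frame with `subject` and `day` per window (row
#'   order must match `labels`/`posterior`), e.g. from
#'   [cohortFeatureTable()].
#' @param labels per-window activity labels for all windows of the cohort.
#' @param posterior per-window posterior matrix aligned with `labels`.
#' @param config,tremorTree,gaitModel,normative forwarded to
#'   [detectSymptoms()].
#' @param inputs optional named (`subject.day`) list of precomputed
#'   [symptomInputs()] (from `cohortFeatureTable(withInputs = TRUE)`);
#'   without it each recording is regenerated from the plan.
#' @param verbose print progress.
#' @return data.frame of per-bin symptoms across the cohort with `subject`,
#'   `day`, `diary_state` and ground-truth columns appended.
#' @export
cohortSymptomTable <- function(plan, featureRows, labels, posterior,
                               config = defaultConfig(),
                               tremorTree = defaultTremorTree(),
                               gaitModel = defaultGaitModel(),
                               normative = NULL, inputs = NULL,
                               verbose = FALSE) {
  out <- list()
  for (i in seq_len(nrow(plan$subjects))) {
    sid <- plan$subjects$subject[i]
    for (d in seq_len(plan$days)) {
      sel <- which(featureRows$subject == sid & featureRows$day == d)
      if (length(sel) == 0) next
      src <- inputs[[paste0(sid, ".", d)]]
      if (is.null(src)) src <- cohortRecording(plan, i, d)$recording
      sy <- detectSymptoms(src, labels[sel],
                           posterior[sel, , drop = FALSE], config,
                           tremorTree, gaitModel, normative)
      df <- sy$bins
      tb <- simTruthBins(plan$profiles[[i]], plan$schedules[[i]][[d]])
      df$subject <- sid; df$day <- d
      df$diary_state <- if (plan$subjects$isControl[i]) "ON" else
        tb$state[match(df$bin, tb$bin)]
      df$true_off <- tb$off[match(df$bin, tb$bin)]
      df$true_gait_severity <- tb$gait_severity[match(df$bin, tb$bin)]
      df$true_speed_mult <- tb$speed_mult[match(df$bin, tb$bin)]
      df$true_dysk <- tb$dysk_eff[match(df$bin, tb$bin)]
      df$true_rom <- 44 - 8 * df$true_gait_severity
      df$true_cadence <- plan$profiles[[i]]$gaitCadence *
        ifelse(df$true_off, 0.85, 1)
      for (limb in c("left_wrist", "right_wrist", "left_ankle", "right_ankle"))
        df[[paste0("true_tremor_", limb)]] <-
          tb[[paste0("tremor_amp_", limb)]][match(df$bin, tb$bin)]
      df$isControl <- plan$subjects$isControl[i]
      out[[length(out) + 1]] <- df
      if (verbose) message(sid, " day ", d, " done")
    }
  }
  do.call(rbind, out)
}

#' Build the multi-day symptom report
#'
#' The "heatmap": per day a bins-x-measures matrix of symptom severities;
#' the "chart": for each 30-minute time-of-day slot, the average of each
#' measure over the days on which that slot has data.
#'
#' @param symptoms per-bin symptom data.frame with `day` and `bin` columns.
#' @param measures measure columns to include (default the main scores).
#' @return list `heatmap` (list of per-day matrices), `chart` (slot x
#'   measure matrix of across-day averages).
#' @export
buildReport <- function(symptoms,
                        measures = c("tremor_lw", "tremor_rw", "tremor_ll",
                                     "tremor_rl", "brady_lw", "brady_rw",
                                     "dyskinesia_score", "gait_score",
                                     "fog_ratio", "p_off")) {
  measures <- intersect(measures, names(symptoms))
  if (!"day" %in% names(symptoms)) symptoms$day <- 1
  days <- sort(unique(symptoms$day))
  slots <- sort(unique(symptoms$bin))
  heat <- lapply(days, function(d) {
    sd <- symptoms[symptoms$day == d, ]
    m <- as.matrix(sd[match(slots, sd$bin), measures, drop = FALSE])
    rownames(m) <- paste0("bin", slots)
    m
  })
  names(heat) <- paste0("day", days)
  arr <- simplify2array(lapply(heat, identity))
  chart <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  list(heatmap = heat, chart = chart)
}

#' Compare device estimates with annotations for every symptom rule
#'
#' For each operating rule: binarize the annotations, apply the configured
#' device threshold to the matching symptom measure, and report the
#' confusion counts and metrics.
#'
#' @param symptoms per-bin symptom table (with `p_off` merged in when OFF is
#'   to be validated).
#' @param ann annotations aligned row-for-row with `symptoms`.
#' @param config configuration (thresholds).
#' @return data.frame: rule, threshold, TP/FN/FP/TN, accuracy, specificity,
#'   sensitivity.
#' @export
validateAgainstAnnotations <- function(symptoms, ann, config = defaultConfig()) {
  stopifnot(nrow(symptoms) == nrow(ann))
  measureOf <- list(
    arm_brady = function(s) pmax(s$brady_lw, s$brady_rw) / 100,
    gait = function(s) s$gait_score,
    wrist_tremor = function(s) pmax(s$tremor_lw, s$tremor_rw),
    leg_tremor = function(s) s$leg_tremor_posterior,
    dyskinesia = function(s) s$dyskinesia_score,
    fog = function(s) s$fog_ratio,
    off = function(s) s$p_off)
  thrOf <- c(arm_brady = config$thresholds$brady, gait = config$thresholds$gait,
             wrist_tremor = config$thresholds$wrist_tremor,
             leg_tremor = config$thresholds$leg_tremor,
             dyskinesia = config$thresholds$dyskinesia,
             fog = config$thresholds$fog, off = config$thresholds$off)
  rules <- names(measureOf)
  rules <- rules[vapply(rules, function(r)
    !is.null(tryCatch(measureOf[[r]](symptoms), error = function(e) NULL)),
    logical(1))]
  out <- lapply(rules, function(r) {
    bz <- binarizeScale(ann, r)
    sc <- measureOf[[r]](symptoms)
    use <- bz$status != "excluded" & !is.na(sc)
    if (!any(use)) return(NULL)
    pos <- bz$status[use] == "positive"
    pred <- sc[use] > thrOf[r]
    cm <- confusionMetrics(sum(pred & pos), sum(!pred & pos),
                           sum(pred & !pos), sum(!pred & !pos))
    data.frame(rule = r, threshold = unname(thrOf[r]),
               TP = cm$counts["TP"], FN = cm$counts["FN"],
               FP = cm$counts["FP"], TN = cm$counts["TN"],
               accuracy = cm$accuracy, specificity = cm$specificity,
               sensitivity = cm$sensitivity, row.names = NULL)
  })
  do.call(rbind, out)
}
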