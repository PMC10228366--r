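# Labeled synthetic IMU simulator: emulates the phenomenology the pipeline
# targets (rest-tremor oscillations at 3.5-8 Hz, gait cycles with the
# TC/RS/IC shank angular-velocity peak structure, band-limited dyskinetic
# movement, pre-walk freezing bursts, posture-dependent gravity, ON/OFF
# severity schedules) so every stage is testable without patient data.

BOUT_TYPES <- c("rest_sit", "rest_lie", "stand", "free_movement",
                "walk_initiation", "walk")

# severity multipliers per medication state; dyskinesia is amplified in ON
# (levodopa-induced), everything else in OFF. Gait/postural deterioration is
# deliberately the strongest OFF effect (PIGD is the dominant OFF correlate
# in this cohort); movement slowing is kept moderate.
STATE_MULT <- list(
  ON = list(tremor = 0.25, dysk = 1, romFactor = 1, cadenceFactor = 1,
             speed = 1, fog = 0.15),
  OFF = list(tremor = 1, dysk = 0.15, romFactor = 0.60, cadenceFactor = 0.85,
             speed = 0.8, fog = 1)
)

LIMBS <- c("left_wrist", "right_wrist", "left_ankle", "right_ankle")

#' Subject profile for the simulator
#'
#' Severity parameters of one simulated subject. A control profile has all
#' symptom gains zero and movement-speed multiplier 1.
#'
#' @param tremorGain named numeric (per limb) peak tremor angular speed, deg/s.
#' @param tremorFreq named numeric per-limb tremor frequency in 3.5-8 Hz.
#' @param gaitRom baseline (ON) shank sagittal range of motion, degrees.
#' @param gaitCadence baseline cadence, steps/min (both feet).
#' @param swingCv swing/stride-time coefficient of variation.
#' @param dyskGain dyskinetic angular-speed RMS, deg/s.
#' @param dyskLimbs limbs expressing dyskinesia (>= 2 when gain > 0).
#' @param fogPropensity probability scale for pre-walk freezing bursts, 0-1.
#' @param speedMult baseline voluntary movement-speed multiplier.
#' @param isControl logical.
#' @return a `subjectProfile` list.
#' @export
subjectProfile <- function(tremorGain = setNames(numeric(4), LIMBS),
                           tremorFreq = setNames(rep(5, 4), LIMBS),
                           gaitRom = 42, gaitCadence = 110, swingCv = 0.03,
                           dyskGain = 0, dyskLimbs = c("left_wrist", "right_wrist", "left_ankle"),
                           fogPropensity = 0, speedMult = 1,
                           isControl = FALSE) {
  if (isControl) {
    stopifnot(all(tremorGain == 0), dyskGain == 0, fogPropensity == 0,
              speedMult == 1)
  }
  if (dyskGain > 0) stopifnot(length(dyskLimbs) >= 2)
  stopifnot(all(tremorFreq >= 3.5 & tremorFreq <= 8))
  structure(list(tremorGain = tremorGain, tremorFreq = tremorFreq,
                 gaitRom = gaitRom, gaitCadence = gaitCadence,
                 swingCv = swingCv, dyskGain = dyskGain,
                 dyskLimbs = dyskLimbs, fogPropensity = fogPropensity,
                 speedMult = speedMult, isControl = isControl),
            class = "subjectProfile")
}

randomProfile <- function(isControl = FALSE) {
  if (isControl) {
    return(subjectProfile(gaitRom = runif(1, 40, 46),
                          gaitCadence = runif(1, 105, 120),
                          swingCv = runif(1, 0.02, 0.04), isControl = TRUE))
  }
  gain <- setNames(numeric(4), LIMBS)
  freq <- setNames(runif(4, 4, 6.5), LIMBS)
  side <- sample(c("left", "right"), 1)
  gain[paste0(side, "_wrist")] <- runif(1, 15, 45)
  if (runif(1) < 0.4) gain[paste0(setdiff(c("left", "right"), side), "_wrist")] <- runif(1, 5, 15)
  if (runif(1) < 0.5) gain[paste0(side, "_ankle")] <- runif(1, 8, 30)
  dysk <- if (runif(1) < 0.6) runif(1, 8, 25) else 0
  subjectProfile(
    tremorGain = gain, tremorFreq = freq,
    gaitRom = runif(1, 32, 44), gaitCadence = runif(1, 95, 115),
    swingCv = runif(1, 0.04, 0.10), dyskGain = dysk,
    dyskLimbs = c("left_wrist", "right_wrist", paste0(side, "_ankle")),
    fogPropensity = if (runif(1) < 0.4) runif(1, 0.5, 0.9) else 0,
    speedMult = runif(1, 0.75, 0.95))
}

#' Build a bout/state schedule
#'
#' Bouts (activity type + duration) tile the session; every duration is a
#' multiple of the 4-s analysis window and the ON/OFF state changes only on
#' 30-minute boundaries, so analysis windows and reporting bins never
#' straddle a ground-truth transition. Controls are always ON.
#'
#' @param hours session length in hours.
#' @param offBins integer bin indices (1-based 30-min bins) spent OFF;
#'   `NULL` draws one contiguous OFF block covering roughly a third of the
#'   session.
#' @param isControl logical; controls get an all-ON timeline.
#' @return a `schedule` list with `bouts` (type, duration_s, start_s) and
#'   `stateBins` (per-bin "ON"/"OFF").
#' @export
makeSchedule <- function(hours = 4, offBins = NULL, isControl = FALSE) {
  totalS <- hours * 3600
  nBins <- ceiling(totalS / 1800)
  if (isControl) {
    state <- rep("ON", nBins)
  } else if (!is.null(offBins)) {
    state <- rep("ON", nBins); state[offBins] <- "OFF"
  } else {
    nOff <- max(1, round(nBins / 3) + sample(-1:1, 1))
    s0 <- sample(seq_len(nBins - nOff + 1), 1)
    state <- rep("ON", nBins); state[s0:(s0 + nOff - 1)] <- "OFF"
  }
  q4 <- function(x) pmax(4, round(x / 4) * 4)
  types <- character(0); durs <- numeric(0)
  tot <- 0
  while (tot < totalS) {
    block <- rbind(
      c("rest_sit", q4(runif(1, 120, 240))),
      c("free_movement", q4(runif(1, 60, 120))),
      c("stand", q4(runif(1, 16, 24))),
      c("walk_initiation", 8),
      c("walk", q4(runif(1, 48, 120))),
      c("rest_sit", q4(runif(1, 60, 180))),
      c("walk_initiation", 8),
      c("walk", q4(runif(1, 40, 80))),
      if (runif(1) < 0.5) c("rest_lie", q4(runif(1, 120, 240))) else
        c("rest_sit", q4(runif(1, 60, 120))),
      c("free_movement", q4(runif(1, 60, 120))))
    types <- c(types, block[, 1]); durs <- c(durs, as.numeric(block[, 2]))
    tot <- sum(durs)
  }
  # truncate to the session and split bouts at 30-min boundaries
  starts <- cumsum(c(0, durs))[seq_along(durs)]
  keep <- starts < totalS
  types <- types[keep]; durs <- durs[keep]; starts <- starts[keep]
  durs[length(durs)] <- totalS - starts[length(starts)]
  outT <- character(0); outD <- numeric(0); outS <- numeric(0)
  for (i in seq_along(types)) {
    s <- starts[i]; e <- starts[i] + durs[i]
    bnd <- seq(0, totalS, by = 1800)
    cuts <- unique(sort(c(s, bnd[bnd > s & bnd < e], e)))
    for (j in seq_len(length(cuts) - 1)) {
      if (cuts[j + 1] - cuts[j] >= 4) {
        outT <- c(outT, types[i]); outS <- c(outS, cuts[j])
        outD <- c(outD, cuts[j + 1] - cuts[j])
      }
    }
  }
  structure(list(bouts = data.frame(type = outT, start_s = outS,
                                    duration_s = outD),
                 stateBins = state, totalS = totalS),
            class = "schedule")
}

gravityVec <- function(position, posture) {
  if (posture == "lying") return(c(0, 0, 1))
  if (posture == "sitting") {
    if (position == "waist") return(c(sin(0.26), cos(0.26), 0)) # ~15 deg recline
    return(c(1, 0, 0))  # shanks horizontal, forearms on lap
  }
  c(0, 1, 0)  # standing/walking: proximal axis up
}

smallRot <- function(v, ang) {
  # rotate v by ang (rad) in the XY plane - enough wobble for realism
  c(cos(ang) * v[1] - sin(ang) * v[2], sin(ang) * v[1] + cos(ang) * v[2], v[3])
}

# per-stride shank angular-velocity template: positive swing lobe (RS)
# flanked by negative TC (heel-off) and IC (heel-strike) lobes; scaled so
# the per-stride sagittal angle range equals `rom` degrees.
strideTemplate <- function(nsamp, fs, rom) {
  tau <- (seq_len(nsamp) - 0.5) / nsamp
  g <- function(mu, s) exp(-0.5 * ((tau - mu) / s)^2)
  u <- g(0.75, 0.045) - 0.55 * g(0.60, 0.030) - 0.55 * g(0.92, 0.025)
  u <- u - mean(u)                      # zero net rotation per stride
  ang <- cumsum(u) / fs
  u * rom / max(diff(range(ang)), 1e-9)
}

#' Simulate one recording with ground truth
#'
#' Generates the five 9-channel streams at the device rate for a profile and
#' schedule, together with per-window activity/posture labels, per-bin true
#' severities and event-level ground truth (stride peak times, wrist
#' movements, freezing bursts). Deterministic for a fixed
#' (profile, schedule, seed).
#'
#' @param profile a [subjectProfile()].
#' @param schedule a [makeSchedule()] result.
#' @param seed integer RNG seed.
#' @param fs sampling rate in Hz.
#' @param subjectId identifier stored in the recording.
#' @return list with `recording` ([IMURecording-class]) and `truth` (list of
#'   `windows`, `bins`, `steps`, `movements`, `fogEvents`).
#' @export
simulateRecording <- function(profile, schedule, seed = 1,
                              fs = IMU_NOMINAL_RATE, subjectId = "sim") {
  set.seed(seed)
  bouts <- schedule$bouts
  n <- round(schedule$totalS / 4) * round(4 * fs)
  magField <- c(0.22, -0.41, 0.13)
  streams <- lapply(IMU_POSITIONS, function(p) {
    # pink (1/f) sensor noise on accelerometer (0.02 g RMS) and gyroscope
    # (1 deg/s RMS); the magnetometer gets white noise around a constant
    # earth-field vector (its channels are validated but unused downstream)
    m <- matrix(rnorm(n * 9), n, 9)
    for (j in 1:3) m[, j] <- 0.02 * pinkFilter(m[, j])
    for (j in 4:6) m[, j] <- pinkFilter(m[, j])
    for (j in 7:9) m[, j] <- 0.005 * m[, j] + magField[j - 6]
    colnames(m) <- IMU_CHANNELS
    m
  })
  names(streams) <- IMU_POSITIONS

  stepsGT <- list(); movesGT <- list(); fogGT <- list()
  winLab <- list()
  wlen <- round(4 * fs)
  stateOf <- function(t) schedule$stateBins[pmin(length(schedule$stateBins),
                                                 floor(t / 1800) + 1)]
  for (b in seq_len(nrow(bouts))) {
    type <- bouts$type[b]
    t0 <- bouts$start_s[b]; dur <- bouts$duration_s[b]
    i0 <- round(t0 / 4) * wlen + 1L
    nb <- round(dur / 4) * wlen
    ii <- seq(i0, length.out = nb)
    tt <- (seq_len(nb) - 1) / fs
    st <- stateOf(t0)
    mult <- STATE_MULT[[st]]
    posture <- switch(type, rest_sit = "sitting", rest_lie = "lying", "standing")
    # gravity on accelerometers, with a small per-bout orientation wobble
    for (p in IMU_POSITIONS) {
      gv <- smallRot(gravityVec(p, posture), runif(1, -0.14, 0.14))
      streams[[p]][ii, 1:3] <- streams[[p]][ii, 1:3] + rep(gv, each = nb)
    }
    tremorActive <- FALSE; dyskActive <- FALSE
    # dyskinesia first: when it is active (medication ON), it dominates the
    # rest-bout phenomenology and rest tremor is suppressed
    if (type == "rest_sit" && profile$dyskGain > 0) {
      D <- profile$dyskGain * mult$dysk
      if (D > 4) {
        dyskActive <- TRUE
        for (limb in profile$dyskLimbs) {
          # band-limited (1-4 Hz) quasi-periodic angular motion: a mixture
          # of random sinusoids, independent across limbs
          s <- 0
          fsin <- runif(10, 1, 4); ph <- runif(10, 0, 2 * pi)
          aw <- abs(rnorm(10)); aw <- aw / sqrt(sum(aw^2) / 2)
          for (q in 1:10) s <- s + aw[q] * sin(2 * pi * fsin[q] * tt + ph[q])
          s <- D * s
          ax <- abs(rnorm(3, c(0.7, 0.5, 0.4), 0.08)); ax <- ax / sqrt(sum(ax^2))
          streams[[limb]][ii, 4:6] <- streams[[limb]][ii, 4:6] + outer(s, ax)
          streams[[limb]][ii, 1:3] <- streams[[limb]][ii, 1:3] + outer(0.002 * s, ax)
        }
      }
    }
    if (!dyskActive && type %in% c("rest_sit", "rest_lie")) {
      # tremor is intermittent: present in a rest bout with a
      # state-dependent probability (its 30-min constancy)
      tremHere <- runif(1) < if (st == "OFF") 0.8 else 0.4
      for (limb in LIMBS) {
        A <- profile$tremorGain[limb] * mult$tremor
        if (A > 3 && tremHere) {
          tremorActive <- TRUE
          f0 <- profile$tremorFreq[limb]
          s <- A * (sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi)) +
                    0.4 * sin(2 * pi * 2 * f0 * tt + runif(1, 0, 2 * pi)))
          s <- s * (1 + 0.25 * sin(2 * pi * 0.3 * tt + runif(1, 0, 2 * pi)))
          ax <- abs(rnorm(3, c(0.8, 0.45, 0.35), 0.05)); ax <- ax / sqrt(sum(ax^2))
          streams[[limb]][ii, 4:6] <- streams[[limb]][ii, 4:6] + outer(s, ax)
          streams[[limb]][ii, 1:3] <- streams[[limb]][ii, 1:3] + outer(s * 0.0015, ax)
        }
      }
    }
    if (type == "walk") {
      rom <- profile$gaitRom * mult$romFactor
      cad <- profile$gaitCadence * mult$cadenceFactor
      strideT <- 120 / cad
      for (side in c("left_ankle", "right_ankle")) {
        off <- if (side == "right_ankle") strideT / 2 else 0.15
        cur <- off
        curs <- numeric(0); tss <- numeric(0)
        while (cur + strideT * 1.2 < dur) {
          Ts <- strideT * max(0.7, 1 + rnorm(1, 0, profile$swingCv))
          ns <- round(Ts * fs)
          if (cur * fs + ns > nb) break
          tpl <- strideTemplate(ns, fs, rom)
          j <- ii[round(cur * fs) + seq_len(ns)]
          streams[[side]][j, 6] <- streams[[side]][j, 6] + tpl
          streams[[side]][j, 4:5] <- streams[[side]][j, 4:5] +
            outer(0.15 * abs(tpl), c(1, 0.7)) * matrix(rnorm(2 * ns, 1, 0.2), ns, 2)
          curs <- c(curs, cur); tss <- c(tss, Ts)
          cur <- cur + Ts
        }
        if (length(curs))
          stepsGT[[length(stepsGT) + 1]] <- data.frame(
            side = side, tc_s = t0 + curs + 0.60 * tss,
            rs_s = t0 + curs + 0.75 * tss, ic_s = t0 + curs + 0.92 * tss,
            stride_s = tss, swing_s = 0.32 * tss)
      }
      stepF <- cad / 60
      streams$waist[ii, 2] <- streams$waist[ii, 2] +
        0.08 * sin(2 * pi * stepF * tt)
      streams$waist[ii, 4:6] <- streams$waist[ii, 4:6] +
        outer(12 * sin(2 * pi * stepF * tt), c(0.5, 0.4, 1))
      for (w in c("left_wrist", "right_wrist")) {
        ph <- if (w == "left_wrist") 0 else pi
        streams[[w]][ii, 4] <- streams[[w]][ii, 4] +
          28 * sin(2 * pi * (cad / 120) * tt + ph)
      }
    }
    if (type == "free_movement") {
      spd <- profile$speedMult * mult$speed
      for (w in c("left_wrist", "right_wrist")) {
        cur <- runif(1, 0.5, 1.5)
        curs <- durs2 <- pks <- numeric(0)
        while (cur < dur - 1.2) {
          mdur <- runif(1, 0.4, 1.0)
          peak <- runif(1, 80, 160) * spd
          ns <- round(mdur * fs)
          j <- ii[round(cur * fs) + seq_len(ns)]
          pulse <- peak * sin(pi * seq_len(ns) / ns)^2
          ax <- abs(rnorm(3, c(0.8, 0.4, 0.3), 0.05)); ax <- ax / sqrt(sum(ax^2))
          streams[[w]][j, 4:6] <- streams[[w]][j, 4:6] + outer(pulse, ax)
          streams[[w]][j, 1:3] <- streams[[w]][j, 1:3] + outer(pulse * 0.002, ax)
          curs <- c(curs, cur); durs2 <- c(durs2, mdur); pks <- c(pks, peak)
          cur <- cur + mdur + runif(1, 1.5, 4)
        }
        if (length(curs))
          movesGT[[length(movesGT) + 1]] <- data.frame(
            limb = w, start_s = t0 + curs, dur_s = durs2, peak_dps = pks)
      }
    }
    if (type == "walk_initiation") {
      pFog <- profile$fogPropensity * mult$fog
      if (runif(1) < pFog) {
        fdur <- 3; f0 <- runif(1, 4, 6)
        fstart <- dur - fdur - 0.5
        j <- round(fstart * fs) + seq_len(round(fdur * fs))
        tf <- (seq_along(j) - 1) / fs
        env <- sin(pi * seq_along(j) / length(j))
        for (side in c("left_ankle", "right_ankle")) {
          s <- 30 * env * sin(2 * pi * f0 * tf + runif(1, 0, 2 * pi))
          streams[[side]][ii[j], 4:6] <- streams[[side]][ii[j], 4:6] +
            outer(s, c(0.5, 0.4, 0.8))
        }
        fogGT[[length(fogGT) + 1]] <- data.frame(start_s = t0 + fstart, dur_s = fdur)
      }
    }
    label <- switch(type,
      walk = "Walking",
      rest_sit = , rest_lie =
        if (dyskActive) "Dyskinetic" else if (tremorActive) "Tremor" else "Resting",
      "Other")
    nw <- round(dur / 4)
    winLab[[b]] <- data.frame(
      start_s = t0 + 4 * (seq_len(nw) - 1), label = label,
      posture = posture, state = st, bout = type)
  }
  lim <- rep(c(8, 2000, 16), each = 3)
  for (p in IMU_POSITIONS) {
    for (j in 1:9) {
      col <- streams[[p]][, j]
      if (max(abs(range(col))) > lim[j])
        streams[[p]][, j] <- pmin(lim[j], pmax(-lim[j], col))
    }
  }
  rec <- IMURecording(subjectId, streams, fs)
  wins <- do.call(rbind, winLab)
  wins <- wins[order(wins$start_s), ]
  wins$window <- seq_len(nrow(wins))
  wins$bin <- floor(wins$start_s / 1800) + 1L
  truth <- list(
    windows = wins,
    bins = simTruthBins(profile, schedule),
    steps = if (length(stepsGT)) do.call(rbind, stepsGT) else NULL,
    movements = if (length(movesGT)) do.call(rbind, movesGT) else NULL,
    fogEvents = if (length(fogGT)) do.call(rbind, fogGT) else NULL)
  list(recording = rec, truth = truth)
}

# per-bin true severities implied by profile x state schedule
simTruthBins <- function(profile, schedule) {
  st <- schedule$stateBins
  out <- data.frame(bin = seq_along(st), state = st, off = st == "OFF")
  dyskOn <- vapply(st, function(s)
    profile$dyskGain * STATE_MULT[[s]]$dysk > 4, logical(1))
  for (limb in LIMBS) {
    amp <- vapply(seq_along(st), function(i) {
      a <- profile$tremorGain[limb] * STATE_MULT[[st[i]]]$tremor
      if (a > 3 && !dyskOn[i]) a else 0   # dyskinesia suppresses rest tremor
    }, numeric(1))
    # RMS of the modulated two-harmonic oscillation, for score ground truth
    out[[paste0("tremor_amp_", limb)]] <- unname(amp * sqrt(1.16 / 2))
  }
  out$gait_severity <- vapply(st, function(s)
    max(0, min(4, (44 - profile$gaitRom * STATE_MULT[[s]]$romFactor) / 8)), numeric(1))
  out$speed_mult <- vapply(st, function(s)
    profile$speedMult * STATE_MULT[[s]]$speed, numeric(1))
  out$dysk_eff <- vapply(st, function(s) {
    d <- profile$dyskGain * STATE_MULT[[s]]$dysk
    if (d > 4) d else 0
  }, numeric(1))
  out$fog_p <- vapply(st, function(s)
    profile$fogPropensity * STATE_MULT[[s]]$fog, numeric(1))
  out
}

#' Simulate a labeled cohort plan
#'
#' Draws subject profiles and per-subject-day seeds deterministically from
#' `seed`. Recordings are not materialized here (a full cohort would not fit
#' in memory); use [cohortRecording()] to generate any subject-day on
#' demand, bit-reproducibly. Defaults: 10 patients + 5 controls, 2 days of
#' 4 h — the study conditions used throughout the package's tests.
#'
#' @param nPatients,nControls cohort composition.
#' @param days recording days per subject.
#' @param hoursPerDay session length.
#' @param seed master seed.
#' @return a `cohortPlan` list: `subjects` data.frame, `profiles`,
#'   `schedules` (per subject-day), `seeds`, and the layout parameters.
#' @export
simulateCohort <- function(nPatients = 10, nControls = 5, days = 2,
                           hoursPerDay = 4, seed = 42) {
  stopifnot(nPatients + nControls >= 1)
  set.seed(seed)
  ids <- c(sprintf("P%02d", seq_len(nPatients)),
           sprintf("C%02d", seq_len(nControls)))
  isControl <- c(rep(FALSE, nPatients), rep(TRUE, nControls))
  profiles <- lapply(isControl, randomProfile)
  schedules <- list(); seeds <- matrix(0L, length(ids), days)
  for (i in seq_along(ids)) {
    schedules[[i]] <- list()
    for (d in seq_len(days)) {
      schedules[[i]][[d]] <- makeSchedule(hoursPerDay, isControl = isControl[i])
      seeds[i, d] <- sample.int(.Machine$integer.max %/% 2, 1)
    }
  }
  names(profiles) <- names(schedules) <- ids
  structure(list(subjects = data.frame(subject = ids, isControl = isControl),
                 profiles = profiles, schedules = schedules, seeds = seeds,
                 days = days, hoursPerDay = hoursPerDay, seed = seed),
            class = "cohortPlan")
}

#' @rdname simulateCohort
#' @param plan a `cohortPlan`.
#' @param subject subject id or index.
#' @param day day index.
#' @return `cohortRecording()`: the [simulateRecording()] result for that
#'   subject-day.
#' @export
cohortRecording <- function(plan, subject, day = 1) {
  i <- if (is.character(subject)) match(subject, plan$subjects$subject) else subject
  stopifnot(!is.na(i), day <= plan$days)
  simulateRecording(plan$profiles[[i]], plan$schedules[[i]][[day]],
                    seed = plan$seeds[i, day],
                    subjectId = plan$subjects$subject[i])
}

#' Cohort-wide labeled feature table
#'
#' Materializes each subject-day in turn, extracts the window feature table
#' and attaches ground-truth labels and identifiers. This is the input for
#' training and leave-one-subject-out evaluation of the activity classifier.
#'
#' @param plan a `cohortPlan`.
#' @param windowS analysis window in seconds.
#' @param withInputs also collect the label-free [symptomInputs()] per
#'   subject-day, so the symptom pipeline can run later without
#'   regenerating any recording (single-pass cohort processing).
#' @param config,tremorTree forwarded to [symptomInputs()] when
#'   `withInputs = TRUE`.
#' @param verbose print progress.
#' @return with `withInputs = FALSE` (default) a data.frame: `subject`,
#'   `day`, `bin`, `label`, `posture`, `state` plus the full feature schema;
#'   otherwise a list `features` (that data.frame) and `inputs` (named
#'   `subject.day` list of symptom inputs).
#' @export
cohortFeatureTable <- function(plan, windowS = 4, withInputs = FALSE,
                               config = defaultConfig(),
                               tremorTree = NULL, verbose = FALSE) {
  if (withInputs && is.null(tremorTree)) tremorTree <- defaultTremorTree()
  out <- list(); inputs <- list()
  for (i in seq_len(nrow(plan$subjects))) {
    for (d in seq_len(plan$days)) {
      sim <- cohortRecording(plan, i, d)
      ft <- buildFeatureTable(sim$recording, windowS)
      gt <- sim$truth$windows
      stopifnot(nrow(ft) == nrow(gt))
      df <- cbind(data.frame(subject = plan$subjects$subject[i], day = d,
                             bin = gt$bin, label = gt$label,
                             posture = gt$posture, state = gt$state),
                  ft)
      out[[length(out) + 1]] <- df
      if (withInputs)
        inputs[[paste0(plan$subjects$subject[i], ".", d)]] <-
          symptomInputs(sim$recording, config, tremorTree)
      if (verbose) message(plan$subjects$subject[i], " day ", d, ": ",
                           nrow(ft), " windows")
    }
  }
  feats <- do.call(rbind, out)
  if (withInputs) list(features = feats, inputs = inputs) else feats
}

#' Synthesize clinician annotations from ground truth
#'
#' Per 30-minute bin, UPDRS/AIMS items and a diary state derived from the
#' true severities through the same anchor tables the forward estimators
#' use (fuzzy tremor map, RoM-to-severity line), which makes parameter
#' recovery well-posed by construction.
#'
#' @param plan a `cohortPlan`.
#' @return data.frame with one row per subject-day-bin in the annotations
#'   CSV schema.
#' @export
cohortAnnotations <- function(plan) {
  out <- list()
  for (i in seq_len(nrow(plan$subjects))) {
    for (d in seq_len(plan$days)) {
      tb <- simTruthBins(plan$profiles[[i]], plan$schedules[[i]][[d]])
      b <- max(0, pmin(4, 6 * (1 - tb$speed_mult)))
      ann <- data.frame(
        subject = plan$subjects$subject[i], day = d,
        bin_start = (tb$bin - 1) * 1800,
        updrs_20_lw = round(amplitudeToUpdrs(tb$tremor_amp_left_wrist)),
        updrs_20_rw = round(amplitudeToUpdrs(tb$tremor_amp_right_wrist)),
        updrs_20_ll = round(amplitudeToUpdrs(tb$tremor_amp_left_ankle)),
        updrs_20_rl = round(amplitudeToUpdrs(tb$tremor_amp_right_ankle)),
        updrs_14 = ifelse(tb$fog_p > 0.4, 2, 0),
        updrs_23 = round(b), updrs_24 = round(b), updrs_25 = round(b),
        updrs_27 = round(0.8 * b), updrs_29 = round(tb$gait_severity),
        updrs_31 = round(0.8 * b),
        aims_total = round(0.55 * tb$dysk_eff),
        diary_state = if (plan$subjects$isControl[i]) "ON" else tb$state)
      out[[length(out) + 1]] <- ann
    }
  }
  do.call(rbind, out)
}

#' Ground-truth severity report for a cohort
#'
#' Machine-readable expected per-bin severities (the acceptance surface for
#' parameter-recovery tests): one row per subject x day x bin.
#'
#' @param plan a `cohortPlan`.
#' @return data.frame of true per-bin severities.
#' @export
groundTruthReport <- function(plan) {
  out <- list()
  for (i in seq_len(nrow(plan$subjects)))
    for (d in seq_len(plan$days)) {
      tb <- simTruthBins(plan$profiles[[i]], plan$schedules[[i]][[d]])
      out[[length(out) + 1]] <- cbind(
        data.frame(subject = plan$subjects$subject[i], day = d), tb)
    }
  do.call(rbind, out)
}

#' Write a simulated dataset to disk
#'
#' Materializes each subject-day as recording CSVs + manifest (the imu_core
#' schema), together with the annotations CSV and the ground-truth report.
#' Intended for small demo cohorts; a full-size cohort is better consumed
#' in memory via [cohortRecording()].
#'
#' @param plan a `cohortPlan`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writeCohort <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(plan$subjects)))
    for (d in seq_len(plan$days)) {
      sim <- cohortRecording(plan, i, d)
      sub <- file.path(dir, sprintf("%s_day%d", plan$subjects$subject[i], d))
      writeRecording(sim$recording, sub)
      write.csv(sim$truth$windows, file.path(sub, "truth_windows.csv"),
                row.names = FALSE)
    }
  write.csv(cohortAnnotations(plan), file.path(dir, "annotations.csv"),
            row.names = FALSE)
  write.csv(groundTruthReport(plan), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
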