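# Resting tremor: 3-s wrist windows, spectral features, CART detection,
# RMS amplitude in the 3.5-8 Hz band, fuzzy linear map to UPDRS item 20.

TREMOR_BAND <- c(3.5, 8)
VOLUNTARY_CUTOFF <- 3

#' Spectral features of a 3-s gyroscope window for tremor detection
#'
#' Features: tri-axial energy of the low-pass (< 3 Hz, voluntary band) and of
#' the band-pass (3.5-8 Hz, tremor band) gyroscope components, their ratio,
#' the dominant frequency of the summed per-axis periodogram within the
#' tremor band, and the sharpness of that spectral peak (peak power over
#' mean tremor-band power).
#'
#' @param g n x 3 gyroscope window (deg/s).
#' @param fs sampling rate (Hz).
#' @return named numeric vector
#'   `low_energy, tremor_energy, ratio, dom_freq, peak_sharpness`.
#' @export
tremorWindowFeatures <- function(g, fs) {
  low <- apply(g, 2, butterFilter, fs = fs, hi = VOLUNTARY_CUTOFF)
  band <- apply(g, 2, butterFilter, fs = fs, lo = TREMOR_BAND[1], hi = TREMOR_BAND[2])
  le <- triAxialEnergy(low)
  te <- triAxialEnergy(band)
  pg <- triAxialSpectrum(g, fs)
  inband <- pg$freq >= TREMOR_BAND[1] & pg$freq <= TREMOR_BAND[2]
  bp <- pg$power[inband]; bf <- pg$freq[inband]
  dom <- if (sum(bp) > 0) bf[which.max(bp)] else 0
  sharp <- if (mean(bp) > 0) max(bp) / mean(bp) else 0
  c(low_energy = le, tremor_energy = te,
    ratio = te / max(le, 1e-9), dom_freq = dom, peak_sharpness = sharp)
}

#' Tremor amplitude of a 3-s window
#'
#' RMS of the 3.5-8 Hz band-passed tri-axial gyroscope signal, in deg/s. For
#' a pure in-band sinusoid of peak angular speed A the value is A/sqrt(2).
#'
#' @inheritParams tremorWindowFeatures
#' @return non-negative amplitude in deg/s.
#' @export
estimateTremorAmplitude <- function(g, fs) {
  band <- apply(g, 2, butterFilter, fs = fs, lo = TREMOR_BAND[1], hi = TREMOR_BAND[2])
  sqrt(mean(rowSums(band^2)))
}

# ---- portable CART tremor tree -------------------------------------------

#' Train the wrist-tremor decision tree on a labeled synthetic corpus
#'
#' A CART tree (depth <= 4, minimum leaf size 20) classifying 3-s windows as
#' tremor / no-tremor from [tremorWindowFeatures()]. The training corpus is
#' synthesized: rest-noise windows, voluntary low-frequency movements of
#' various amplitudes, and tremor oscillations spanning 3.5-8 Hz and a range
#' of amplitudes. The fitted tree is converted to a portable node table so
#' inference does not depend on the fitting machinery and is deterministic.
#'
#' @param nPerClass windows per class (default 400).
#' @param seed RNG seed for corpus generation.
#' @param fs sampling rate (Hz).
#' @return a `tremorTree`: data.frame of nodes with columns `id, var, split,
#'   left, right, pred` (leaf rows have `NA` var).
#' @export
fitTremorTree <- function(nPerClass = 400, seed = 1, fs = IMU_NOMINAL_RATE) {
  set.seed(seed)
  n <- round(3 * fs)
  t <- seq_len(n) / fs
  gen <- function(kind) {
    g <- matrix(rnorm(3 * n, sd = runif(1, 0.5, 2)), n, 3)
    if (kind == "voluntary") {
      f <- runif(1, 0.3, 2.5); a <- runif(1, 20, 150)
      ax <- runif(3); ax <- ax / sqrt(sum(ax^2))
      if (runif(1) < 0.5) {
        g <- g + outer(a * sin(2 * pi * f * t + runif(1, 0, 2 * pi)), ax)
      } else {
        # harmonic-rich discrete movement pulses (squared-sine bursts)
        s <- numeric(n); cur <- runif(1, 0, 0.4)
        while (cur < 3 - 0.3) {
          mdur <- runif(1, 0.25, 0.8)
          ns <- min(round(mdur * fs), n - round(cur * fs))
          jj <- round(cur * fs) + seq_len(ns)
          s[jj] <- s[jj] + a * sin(pi * seq_len(ns) / ns)^2 * sample(c(-1, 1), 1)
          cur <- cur + mdur + runif(1, 0.1, 0.8)
        }
        g <- g + outer(s, ax)
      }
    } else if (kind == "tremor") {
      f <- runif(1, 3.5, 8); a <- runif(1, 3, 60)
      ax <- runif(3); ax <- ax / sqrt(sum(ax^2))
      s <- a * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
        0.3 * a * sin(2 * pi * 2 * f * t)
      s <- s * (1 + 0.3 * sin(2 * pi * 0.4 * t))
      g <- g + outer(s, ax)
      if (runif(1) < 0.3) { # tremor superimposed on mild voluntary drift
        fv <- runif(1, 0.3, 1.5)
        g <- g + outer(runif(1, 5, 30) * sin(2 * pi * fv * t), runif(3))
      }
    }
    g
  }
  kinds <- c(rep("rest", ceiling(nPerClass / 2)),
             rep("voluntary", floor(nPerClass / 2)),
             rep("tremor", nPerClass))
  feats <- t(vapply(kinds, function(k) tremorWindowFeatures(gen(k), fs),
                    numeric(5)))
  df <- as.data.frame(feats)
  df$y <- factor(ifelse(kinds == "tremor", "tremor", "none"),
                 levels = c("none", "tremor"))
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(maxdepth = 4, minbucket = 20,
                                                     cp = 0.002, xval = 0))
  rpartToTable(fit)
}

rpartToTable <- function(fit) {
  fr <- fit$frame
  ids <- as.integer(rownames(fr))
  sp <- fit$splits
  tbl <- data.frame(id = ids, var = as.character(fr$var), split = NA_real_,
                    dir = NA_character_, left = NA_integer_, right = NA_integer_,
                    pred = attr(fit, "ylevels")[fr$yval],
                    stringsAsFactors = FALSE)
  srow <- 1
  for (i in seq_len(nrow(fr))) {
    if (fr$var[i] != "<leaf>") {
      # primary split is the first of the ncompete+1 rows for this node
      tbl$split[i] <- sp[srow, "index"]
      if (abs(sp[srow, "ncat"]) != 1) stop("categorical splits unsupported")
      # ncat == -1: x < split goes left; ncat == +1: x >= split goes left
      tbl$dir[i] <- if (sp[srow, "ncat"] < 0) "lt" else "ge"
      tbl$left[i] <- 2L * ids[i]
      tbl$right[i] <- 2L * ids[i] + 1L
      srow <- srow + fr$ncompete[i] + fr$nsurrogate[i] + 1
    } else {
      tbl$var[i] <- NA_character_
    }
  }
  class(tbl) <- c("tremorTree", "data.frame")
  tbl
}

#' @rdname fitTremorTree
#' @param tree a `tremorTree` node table.
#' @param path file path for the YAML persistence.
#' @export
writeTremorTree <- function(tree, path) {
  yaml::write_yaml(lapply(seq_len(nrow(tree)), function(i) as.list(tree[i, ])),
                   path, precision = 15)
  invisible(path)
}

#' @rdname fitTremorTree
#' @export
readTremorTree <- function(path) {
  rows <- yaml::read_yaml(path)
  grab <- function(r, k, cast) if (is.null(r[[k]]) || is.na(r[[k]])) cast(NA) else cast(r[[k]])
  tbl <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = as.integer(r$id),
               var = grab(r, "var", as.character),
               split = grab(r, "split", as.numeric),
               dir = grab(r, "dir", as.character),
               left = grab(r, "left", as.integer),
               right = grab(r, "right", as.integer),
               pred = r$pred, stringsAsFactors = FALSE)
  }))
  class(tbl) <- c("tremorTree", "data.frame")
  tbl
}

#' @rdname fitTremorTree
#' @param x feature data.frame / named vector to classify.
#' @return `predictTremorTree()`: character vector of predicted labels.
#' @export
predictTremorTree <- function(tree, x) {
  if (is.null(dim(x))) x <- as.data.frame(as.list(x))
  vapply(seq_len(nrow(x)), function(i) {
    id <- 1L
    repeat {
      node <- tree[tree$id == id, ]
      if (is.na(node$var)) return(node$pred)
      goLeft <- if (node$dir == "ge") x[[node$var]][i] >= node$split
                else x[[node$var]][i] < node$split
      id <- if (goLeft) node$left else node$right
    }
  }, character(1))
}

defaultTremorTree <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- readTremorTree(system.file("extdata", "tremor_tree.yaml",
                                           package = "pdmotor", mustWork = TRUE))
    cache
  }
})

#' Detect resting tremor in one 3-s wrist window
#'
#' Classifies the window with the (persisted) CART tree on the spectral
#' features, reports the dominant frequency in the 3.5-8 Hz band and the
#' band-passed RMS amplitude. The window must be 3 s (within one sample).
#'
#' @param g n x 3 wrist gyroscope window (deg/s).
#' @param fs sampling rate (Hz).
#' @param tree tremor tree (default: the tree shipped with the package).
#' @return data.frame row: `present`, `dominant_freq` (Hz), `amplitude`
#'   (deg/s RMS).
#' @export
detectWristTremor <- function(g, fs, tree = defaultTremorTree()) {
  if (abs(nrow(g) - round(3 * fs)) > 1)
    stop("tremor detection requires a 3-s window")
  f <- tremorWindowFeatures(g, fs)
  present <- predictTremorTree(tree, f) == "tremor"
  data.frame(present = present, dominant_freq = unname(f["dom_freq"]),
             amplitude = estimateTremorAmplitude(g, fs))
}

#' Fuzzy linear map from tremor amplitude to UPDRS item 20
#'
#' Piecewise-linear interpolation between amplitude-score anchor pairs,
#' clipped to the 0-4 item range. Default anchors (deg/s RMS -> score):
#' 0->0, 5->1, 15->2, 35->3, 60->4.
#'
#' @param amplitude numeric vector of amplitudes (deg/s RMS).
#' @param map data.frame with strictly increasing `amplitude` and
#'   non-decreasing `score` columns.
#' @return scores in \[0, 4\].
#' @export
amplitudeToUpdrs <- function(amplitude, map = defaultFuzzyMap()) {
  stopifnot(all(diff(map$amplitude) > 0), all(diff(map$score) >= 0))
  pmin(4, pmax(0, approx(map$amplitude, map$score, xout = amplitude,
                         rule = 2)$y))
}

#' @rdname amplitudeToUpdrs
#' @export
defaultFuzzyMap <- function() {
  data.frame(amplitude = c(0, 5, 15, 35, 60), score = c(0, 1, 2, 3, 4))
}

#' Aggregate wrist-tremor detections over a 30-minute bin
#'
#' Constancy is the fraction of windows with tremor present; the bin score is
#' the fuzzy-map value of the median amplitude over detected windows, forced
#' to 0 when constancy is below `minConstancy` (tremor must occupy at least
#' that fraction of the bin).
#'
#' @param det data.frame of per-window detections ([detectWristTremor()]
#'   rows) for one bin.
#' @param map fuzzy linear map.
#' @param minConstancy minimum constancy for a nonzero score (default 0.25).
#' @return list `score` (0-4), `constancy` (0-1); both `NA` for an empty bin.
#' @export
wristTremor30 <- function(det, map = defaultFuzzyMap(), minConstancy = 0.25) {
  if (is.null(det) || nrow(det) == 0)
    return(list(score = NA_real_, constancy = NA_real_))
  constancy <- mean(det$present)
  score <- if (constancy >= minConstancy && any(det$present))
    amplitudeToUpdrs(median(det$amplitude[det$present]), map)
  else 0
  list(score = score, constancy = constancy)
}

#' Leg tremor: mean Tremor posterior over a 30-minute bin
#'
#' The activity classifier's posterior for the Tremor class mainly reflects
#' leg activity; its arithmetic mean over a bin is the leg-tremor measure
#' (operating threshold 0.16).
#'
#' @param pTremor numeric vector of per-window `P(Tremor | X)` for the bin.
#' @return mean posterior in \[0, 1\], `NA` for an empty bin.
#' @export
legTremor30 <- function(pTremor) {
  if (length(pTremor) == 0) return(NA_real_)
  mean(pTremor)
}
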