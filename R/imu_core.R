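#' Read a multi-device recording from CSV files plus a YAML manifest
#'
#' The manifest gives `subject_id`, `sampling_rate`, `start_time` (ISO-8601)
#' and a `files:` map from each of the five positions to a per-position CSV
#' with columns `t_s,ax_g,ay_g,az_g,gx_dps,gy_dps,gz_dps,mx_gauss,my_gauss,
#' mz_gauss`. Streams are synchronized onto a common uniform clock (see
#' [synchronizeStreams()]) before validation, so streams whose clocks differ
#' are trimmed/resampled to their overlap.
#'
#' @param manifestPath path to the YAML manifest.
#' @return a validated [IMURecording-class].
#' @seealso [writeRecording()] for the inverse.
#' @export
readRecording <- function(manifestPath) {
  man <- yaml::read_yaml(manifestPath)
  need <- c("subject_id", "files", "sampling_rate", "start_time")
  if (!all(need %in% names(man)))
    stop("manifest must contain: ", paste(need, collapse = ", "))
  missing <- setdiff(IMU_POSITIONS, names(man$files))
  if (length(missing))
    stop("missing position: ", paste(missing, collapse = ", "))
  base <- dirname(manifestPath)
  cols <- c("t_s", paste0(c("ax", "ay", "az"), "_g"),
            paste0(c("gx", "gy", "gz"), "_dps"),
            paste0(c("mx", "my", "mz"), "_gauss"))
  raw <- list()
  for (pos in IMU_POSITIONS) {
    f <- man$files[[pos]]
    path <- if (file.exists(f)) f else file.path(base, f)
    df <- read.csv(path, check.names = FALSE)
    if (!identical(names(df), cols))
      stop(pos, ": malformed header, expected columns ", paste(cols, collapse = ","))
    bad <- which(!complete.cases(df) | !apply(df, 1, function(r) all(is.finite(r))))
    if (length(bad))
      stop(pos, ": malformed row at line ", bad[1] + 1L)
    m <- as.matrix(df[, -1])
    colnames(m) <- IMU_CHANNELS
    lim <- rep(IMU_FULL_SCALE, each = 3)
    over <- which(apply(abs(m), 2, max) > lim)
    if (length(over))
      stop(pos, ": channel ", IMU_CHANNELS[over[1]],
           " out of range (full scale ", lim[over[1]], ")")
    raw[[pos]] <- list(t = df$t_s, samples = m)
  }
  synchronizeStreams(raw, subjectId = man$subject_id,
                     samplingRate = man$sampling_rate,
                     startTime = as.POSIXct(man$start_time, tz = "UTC"))
}

#' Write a recording to per-position CSV files plus a YAML manifest
#'
#' Values are written with full precision (`%.17g`) so that a read/write/read
#' round trip reproduces the samples bit-exactly.
#'
#' @param rec an [IMURecording-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
writeRecording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t_s <- (seq_len(length(rec)) - 1) / rec@samplingRate
  files <- list()
  cols <- c("t_s", paste0(c("ax", "ay", "az"), "_g"),
            paste0(c("gx", "gy", "gz"), "_dps"),
            paste0(c("mx", "my", "mz"), "_gauss"))
  for (pos in IMU_POSITIONS) {
    f <- paste0(pos, ".csv")
    m <- cbind(t_s, rec@streams[[pos]])
    con <- file(file.path(dir, f), "w")
    writeLines(paste(cols, collapse = ","), con)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")), con)
    close(con)
    files[[pos]] <- f
  }
  man <- list(subject_id = rec@subjectId, sampling_rate = rec@samplingRate,
              start_time = format(rec@startTime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
              files = files)
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, mp)
  invisible(mp)
}

#' Synchronize raw per-position streams onto a shared uniform clock
#'
#' Streams arrive with their own sample clocks (`t` in seconds). They are
#' linearly interpolated onto a uniform grid at `samplingRate`, starting at
#' the latest common start time and ending at the earliest common end time.
#' Streams already on that grid pass through unchanged, so the operation is
#' idempotent.
#'
#' @param raw named list (all five positions) of lists with `t` (seconds) and
#'   `samples` (n x 9 matrix).
#' @param subjectId,samplingRate,startTime recording metadata.
#' @return a validated [IMURecording-class].
#' @export
synchronizeStreams <- function(raw, subjectId = "anon",
                               samplingRate = IMU_NOMINAL_RATE,
                               startTime = as.POSIXct("2000-01-01", tz = "UTC")) {
  missing <- setdiff(IMU_POSITIONS, names(raw))
  if (length(missing))
    stop("missing position: ", paste(missing, collapse = ", "))
  t0 <- max(vapply(raw, function(s) s$t[1], numeric(1)))
  t1 <- min(vapply(raw, function(s) s$t[length(s$t)], numeric(1)))
  if (t1 - t0 <= 0) stop("streams have no temporal overlap")
  grid <- seq(t0, t1, by = 1 / samplingRate)
  streams <- lapply(raw[IMU_POSITIONS], function(s) {
    if (length(s$t) == length(grid) && max(abs(s$t - grid)) < 1e-9) {
      m <- s$samples
    } else {
      m <- apply(s$samples, 2, function(ch) approx(s$t, ch, xout = grid)$y)
    }
    colnames(m) <- IMU_CHANNELS
    m
  })
  IMURecording(subjectId, streams, samplingRate,
               startTime = startTime + t0)
}

#' Segment a recording into fixed-length analysis windows
#'
#' Windows tile the recording from the start; the trailing partial window is
#' dropped. Intervals are half-open `[start, end)`. The 4-s window is the
#' basic unit for activity detection; 3-s windows are used for wrist tremor.
#'
#' @param rec an [IMURecording-class] (or an integer sample count, with
#'   `fs` supplied, for testing window arithmetic).
#' @param windowS window duration in seconds (> 0).
#' @param hopS hop between window starts in seconds (default `windowS`,
#'   i.e. non-overlapping tiling).
#' @param fs sampling rate override when `rec` is a sample count.
#' @return data.frame with `window` (1-based index), `start_sample` (1-based),
#'   `n_samples`, `start_s`. Zero rows when the recording is shorter than one
#'   window.
#' @export
segmentWindows <- function(rec, windowS = 4, hopS = windowS, fs = NULL) {
  stopifnot(windowS > 0, hopS > 0)
  if (is(rec, "IMURecording")) {
    n <- length(rec); fs <- rec@samplingRate
  } else {
    n <- as.integer(rec)
    if (is.null(fs)) stop("fs required when rec is a sample count")
  }
  wlen <- round(windowS * fs)
  hop <- round(hopS * fs)
  if (n < wlen)
    return(data.frame(window = integer(), start_sample = integer(),
                      n_samples = integer(), start_s = numeric()))
  nwin <- floor((n - wlen) / hop) + 1
  starts <- (seq_len(nwin) - 1L) * hop + 1L
  data.frame(window = seq_len(nwin), start_sample = starts,
             n_samples = wlen, start_s = (starts - 1L) / fs)
}

#' Assign analysis windows to 30-minute reporting bins
#'
#' A window belongs to the bin containing its start time; bins are half-open
#' `[start, end)` intervals aligned to the recording start, so a window
#' starting exactly on a boundary belongs to the later bin.
#'
#' @param windows data.frame from [segmentWindows()].
#' @param binMinutes bin length in minutes (default 30).
#' @return `windows` with a `bin` column (1-based ordinal).
#' @export
assignBins <- function(windows, binMinutes = 30) {
  if (nrow(windows) == 0) {
    windows$bin <- integer()
    return(windows)
  }
  windows$bin <- floor(windows$start_s / (binMinutes * 60)) + 1L
  windows
}

# Extract one window (samples x 9) of a position's stream.
windowMatrix <- function(rec, position, win) {
  m <- imuStream(rec, position)
  idx <- seq(win$start_sample, length.out = win$n_samples)
  m[idx, , drop = FALSE]
}
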