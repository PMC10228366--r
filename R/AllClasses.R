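#' @import methods
NULL

#' IMURecording: synchronized multi-device inertial recording
#'
#' Container for one subject-session of synchronized 9-axis IMU data from the
#' five body positions (left/right wrist, left/right ankle, waist). Each
#' stream is a numeric matrix with one row per sample and the nine channels
#' `ax,ay,az` (g), `gx,gy,gz` (deg/s), `mx,my,mz` (gauss). Validity enforces
#' the five-position layout, equal stream lengths (the streams are assumed to
#' share one uniform clock after synchronization) and the device full scales
#' (accelerometer within ±8 g, gyroscope within ±2000 deg/s, magnetometer
#' within ±16 gauss).
#'
#' @slot subjectId character scalar, opaque subject identifier.
#' @slot streams named list of 5 numeric matrices (samples x 9 channels).
#' @slot samplingRate sampling rate in Hz (nominal 59.5).
#' @slot startTime recording start as `POSIXct`.
#'
#' @export
setClass("IMURecording",
  representation(
    subjectId = "character",
    streams = "list",
    samplingRate = "numeric",
    startTime = "POSIXct"
  )
)

setValidity("IMURecording", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1) msg <- c(msg, "subjectId must be a single string")
  if (!setequal(names(object@streams), IMU_POSITIONS) ||
      length(object@streams) != 5) {
    missing <- setdiff(IMU_POSITIONS, names(object@streams))
    msg <- c(msg, paste0("streams must cover exactly the 5 positions; missing position: ",
                         paste(missing, collapse = ", ")))
  } else {
    lens <- vapply(object@streams, nrow, integer(1))
    if (length(unique(lens)) != 1)
      msg <- c(msg, "all streams must have equal length after synchronization")
    for (pos in IMU_POSITIONS) {
      m <- object@streams[[pos]]
      if (!is.matrix(m) || ncol(m) != 9 || !identical(colnames(m), IMU_CHANNELS)) {
        msg <- c(msg, paste0(pos, ": stream must be a samples x 9 matrix with channels ",
                             paste(IMU_CHANNELS, collapse = ",")))
        next
      }
      lim <- rep(IMU_FULL_SCALE, each = 3)
      bad <- which(apply(abs(m), 2, max) > lim + 1e-9)
      if (length(bad))
        msg <- c(msg, paste0(pos, ": channel ", IMU_CHANNELS[bad[1]],
                             " exceeds device full scale (",
                             lim[bad[1]], ")"))
      if (any(!is.finite(m)))
        msg <- c(msg, paste0(pos, ": non-finite sample values"))
    }
  }
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct an IMURecording
#'
#' @param subjectId subject identifier.
#' @param streams named list of 5 samples-x-9 matrices (see class docs).
#' @param samplingRate sampling rate in Hz.
#' @param startTime `POSIXct` start time (default epoch origin, UTC).
#' @return validated [IMURecording-class] object.
#' @export
IMURecording <- function(subjectId, streams, samplingRate = IMU_NOMINAL_RATE,
                         startTime = as.POSIXct("2000-01-01", tz = "UTC")) {
  new("IMURecording", subjectId = subjectId, streams = streams[IMU_POSITIONS],
      samplingRate = samplingRate, startTime = startTime)
}

#' @describeIn IMURecording-class number of samples per stream
#' @param x,object an `IMURecording`.
#' @export
setMethod("length", "IMURecording", function(x) nrow(x@streams[[1]]))

setMethod("show", "IMURecording", function(object) {
  n <- length(object)
  cat(sprintf("IMURecording '%s': %d samples x 5 positions x 9 channels\n",
              object@subjectId, n))
  cat(sprintf("  %.1f Hz, duration %.1f min, start %s\n", object@samplingRate,
              n / object@samplingRate / 60, format(object@startTime)))
})

#' Accessors for IMURecording
#'
#' @param rec an [IMURecording-class].
#' @param position one of the five body positions.
#' @return `imuStream()` the samples-x-9 matrix for one position;
#'   `subjectId()` the subject identifier; `samplingRate()` the rate in Hz;
#'   `duration()` the recording length in seconds.
#' @export
imuStream <- function(rec, position) {
  position <- match.arg(position, IMU_POSITIONS)
  rec@streams[[position]]
}

#' @rdname imuStream
#' @export
subjectId <- function(rec) rec@subjectId

#' @rdname imuStream
#' @export
samplingRate <- function(rec) rec@samplingRate

#' @rdname imuStream
#' @export
duration <- function(rec) length(rec) / rec@samplingRate

#' ActivityModel: wrapper-selected Gaussian Naive Bayes activity classifier
#'
#' Per-class Gaussian mean/variance for each selected feature plus class
#' priors. Variances are floored at `varFloorFrac` of the pooled variance of
#' the feature so degenerate (constant-within-class) features cannot produce
#' infinite densities.
#'
#' @slot features character, selected feature names.
#' @slot classes character, class labels in fixed order.
#' @slot means,vars numeric matrices (classes x features).
#' @slot priors named numeric vector summing to 1.
#' @slot varFloorFrac numeric scalar.
#' @export
setClass("ActivityModel",
  representation(
    features = "character", classes = "character",
    means = "matrix", vars = "matrix", priors = "numeric",
    varFloorFrac = "numeric"
  )
)

setValidity("ActivityModel", function(object) {
  msg <- character()
  if (abs(sum(object@priors) - 1) > 1e-8) msg <- c(msg, "priors must sum to 1")
  if (any(object@vars <= 0)) msg <- c(msg, "variances must be positive (floored)")
  if (!identical(dim(object@means), dim(object@vars)))
    msg <- c(msg, "means and vars must have identical dimensions")
  if (nrow(object@means) != length(object@classes) ||
      ncol(object@means) != length(object@features))
    msg <- c(msg, "parameter matrices must be classes x features")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ActivityModel", function(object) {
  cat(sprintf("ActivityModel: %d classes, %d selected features\n",
              length(object@classes), length(object@features)))
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  cat("  features:", paste(head(object@features, 6), collapse = ", "),
      if (length(object@features) > 6) "..." else "", "\n")
})

#' Accessors for ActivityModel / OffModel
#' @param model a model object.
#' @return `modelFeatures()` selected feature names; `modelPriors()` class
#'   priors.
#' @export
modelFeatures <- function(model) model@features

#' @rdname modelFeatures
#' @export
modelPriors <- function(model) model@priors

#' OffModel: Gaussian Naive Bayes over per-bin symptom vectors
#'
#' Same parameterization as [ActivityModel-class] but over the 30-minute
#' symptom vector, with two classes (ON/OFF) and per-feature missing-data
#' support: features absent from a bin are omitted from the likelihood
#' product rather than imputed.
#'
#' @slot features,classes,means,vars,priors,varFloorFrac see
#'   [ActivityModel-class].
#' @export
setClass("OffModel", contains = "ActivityModel")

setMethod("show", "OffModel", function(object) {
  cat(sprintf("OffModel: Gaussian Naive Bayes over %d symptom features\n",
              length(object@features)))
  cat("  priors:", paste(sprintf("%s=%.3f", object@classes, object@priors),
                         collapse = ", "), "\n")
})
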