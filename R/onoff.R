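# OFF-state estimation: Gaussian Naive Bayes over the assembled per-bin
# symptom vector, OFF-time fraction, and ReliefF feature importance.

#' The fixed OFF-feature schema and its groups
#'
#' Order of the per-bin symptom vector consumed by the OFF classifier, with
#' the group each feature belongs to: Activity (lack of movement, activity
#' level, resting time), Gait (gait score, gait score excluding dyskinetic
#' intervals), Tremor (four limbs), FoG/postural instability (FoG ratio) and
#' Arm bradykinesia (two wrists).
#'
#' @return named character vector: names are feature names, values groups.
#' @export
offFeatureGroups <- function() {
  c(lack_of_movement = "Activity", activity_level = "Activity",
    resting_time = "Activity",
    gait_score = "Gait", gait_score_nodysk = "Gait",
    tremor_ll = "Tremor", tremor_rl = "Tremor",
    tremor_lw = "Tremor", tremor_rw = "Tremor",
    fog_ratio = "FoG/PI",
    brady_lw = "Arm bradykinesia", brady_rw = "Arm bradykinesia")
}

#' Assemble per-bin symptom vectors in the fixed schema order
#'
#' Selects and orders the OFF-feature columns from a per-bin symptom table
#' (see [detectSymptoms()]). Missing values stay `NA` — an explicit no-data
#' marker that downstream likelihoods omit rather than impute.
#'
#' @param symptoms per-bin symptom data.frame.
#' @return data.frame with any identifier columns (`subject`, `day`, `bin`)
#'   followed by the 12 schema features.
#' @export
assembleSymptomVectors <- function(symptoms) {
  feats <- names(offFeatureGroups())
  miss <- setdiff(feats, names(symptoms))
  if (length(miss)) stop("symptom table lacks: ", paste(miss, collapse = ", "))
  ids <- intersect(c("subject", "day", "bin"), names(symptoms))
  symptoms[, c(ids, feats)]
}

#' Fit the OFF-state Naive Bayes model
#'
#' Gaussian class-conditionals per symptom feature with per-feature
#' missing-data handling: a bin's `NA` entries simply do not contribute to
#' that feature's parameter estimates, and at prediction time are skipped in
#' the likelihood product.
#'
#' @param vectors data.frame from [assembleSymptomVectors()].
#' @param labels per-bin diary state, "ON"/"OFF" (bins with `NA` are
#'   dropped).
#' @param varFloorFrac variance floor fraction.
#' @return an [OffModel-class].
#' @export
fitOff <- function(vectors, labels, varFloorFrac = 1e-4) {
  feats <- names(offFeatureGroups())
  keep <- !is.na(labels)
  X <- as.matrix(vectors[keep, feats])
  y <- factor(labels[keep], levels = c("ON", "OFF"))
  if (nlevels(droplevels(y)) < 2) stop("both ON and OFF bins are required")
  classes <- c("ON", "OFF")
  means <- vars <- matrix(NA_real_, 2, length(feats),
                          dimnames = list(classes, feats))
  for (j in seq_along(feats)) {
    x <- X[, j]
    pooled <- var(x, na.rm = TRUE)
    if (!is.finite(pooled) || pooled <= 0) pooled <- 1
    for (k in 1:2) {
      xv <- x[y == classes[k] & !is.na(x)]
      means[k, j] <- if (length(xv)) mean(xv) else mean(x, na.rm = TRUE)
      v <- if (length(xv) >= 2) var(xv) else pooled
      vars[k, j] <- max(v, varFloorFrac * pooled, 1e-12)
    }
  }
  pri <- table(y) / length(y)
  new("OffModel", features = feats, classes = classes, means = means,
      vars = vars, priors = setNames(as.numeric(pri), classes),
      varFloorFrac = varFloorFrac)
}

#' Per-bin OFF probability
#'
#' Normalized Naive Bayes posterior for the OFF state. Features that are
#' `NA` in a bin are omitted from the likelihood product; a bin with no
#' available features gets an `NA` estimate. Flags are reported at the
#' detection threshold (0.5) and the OFF-time threshold (0.55).
#'
#' @param model an [OffModel-class].
#' @param vectors data.frame containing the schema features.
#' @return data.frame `p_off, off_flag_05, off_flag_055`.
#' @export
offProbability <- function(model, vectors) {
  feats <- model@features
  X <- as.matrix(vectors[, feats])
  lp <- matrix(rep(log(model@priors), each = nrow(X)), nrow(X), 2)
  for (j in seq_along(feats)) {
    x <- X[, j]
    ok <- !is.na(x)
    for (k in 1:2) {
      m <- model@means[k, j]; v <- model@vars[k, j]
      lp[ok, k] <- lp[ok, k] - 0.5 * log(2 * pi * v) - (x[ok] - m)^2 / (2 * v)
    }
  }
  p <- logPostToProb(lp)[, 2]
  p[rowSums(!is.na(X)) == 0] <- NA_real_
  data.frame(p_off = p, off_flag_05 = p > 0.5, off_flag_055 = p > 0.55)
}

#' Fraction of time in the OFF state
#'
#' Ratio of bins whose OFF probability strictly exceeds `threshold` (0.55,
#' the OFF-time operating point) to the number of bins with a valid
#' estimate.
#'
#' @param pOff per-bin OFF probabilities (NA = no data).
#' @param threshold strict threshold (default 0.55).
#' @return fraction in \[0, 1\], `NA` when no bin is valid.
#' @export
offTimeFraction <- function(pOff, threshold = 0.55) {
  ok <- !is.na(pOff)
  if (!any(ok)) return(NA_real_)
  mean(pOff[ok] > threshold)
}

#' ReliefF feature importance for OFF detection
#'
#' ReliefF with k nearest hits/misses per instance, run over all complete
#' instances, features min-max scaled to \[0, 1\] beforehand (so weights are
#' comparable across units). A feature's weight grows when its values
#' separate opposite-class neighbors and shrink when they differ between
#' same-class neighbors. Group importances are the means of member-feature
#' weights over the Table-of-interest groups ([offFeatureGroups()]).
#'
#' @param vectors data.frame with the schema features (rows with any `NA`
#'   are dropped: the strict gait-available filter).
#' @param labels per-row class labels (two classes).
#' @param k neighbor count (default 10).
#' @param seed RNG seed (used only for instance-order shuffling; results
#'   are reproducible bit-exactly for a fixed seed).
#' @return list `features` (feature, weight, group) sorted by schema order,
#'   and `groups` (group, weight) sorted by decreasing weight.
#' @export
reliefImportance <- function(vectors, labels, k = 10, seed = 1) {
  feats <- intersect(names(offFeatureGroups()), names(vectors))
  X <- as.matrix(vectors[, feats])
  ok <- complete.cases(X) & !is.na(labels)
  X <- X[ok, , drop = FALSE]
  y <- as.character(labels)[ok]
  if (min(table(y)) < 2 * k)
    stop("need at least 2k samples per class for ReliefF")
  rng <- apply(X, 2, function(x) diff(range(x)))
  rng[rng == 0] <- 1
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  set.seed(seed)
  ord <- sample(nrow(Xs))
  m <- nrow(Xs)
  W <- numeric(ncol(Xs))
  D <- as.matrix(dist(Xs, method = "manhattan"))
  for (i in ord) {
    same <- which(y == y[i]); same <- same[same != i]
    diffc <- which(y != y[i])
    hits <- same[order(D[i, same])][seq_len(min(k, length(same)))]
    misses <- diffc[order(D[i, diffc])][seq_len(min(k, length(diffc)))]
    W <- W - colSums(abs(Xs[hits, , drop = FALSE] -
                           rep(Xs[i, ], each = length(hits)))) / (m * length(hits)) +
      colSums(abs(Xs[misses, , drop = FALSE] -
                    rep(Xs[i, ], each = length(misses)))) / (m * length(misses))
  }
  fdf <- data.frame(feature = feats, weight = W,
                    group = unname(offFeatureGroups()[feats]))
  gw <- aggregate(weight ~ group, fdf, mean)
  gw <- gw[order(-gw$weight), ]
  list(features = fdf, groups = gw)
}
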