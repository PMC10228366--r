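# Gaussian Naive Bayes machinery shared by the activity and OFF classifiers.
# Variances are floored at varFloorFrac * pooled variance per feature.

nbParams <- function(X, y, varFloorFrac = 1e-6) {
  lv <- levels(y)
  n <- nrow(X)
  cnt <- as.vector(table(y))
  S1 <- rowsum(X, y)            # class sums, classes x features
  S2 <- rowsum(X^2, y)
  means <- S1 / cnt
  vars <- (S2 - cnt * means^2) / pmax(cnt - 1, 1)
  mu <- colMeans(X)
  pooled <- (colSums(X^2) - n * mu^2) / (n - 1)
  floorv <- pmax(varFloorFrac * pooled, 1e-12)
  vars <- pmax(vars, rep(floorv, each = length(lv)))
  list(means = means, vars = vars, priors = setNames(cnt / n, lv), classes = lv)
}

nbLogPosterior <- function(params, X) {
  lv <- params$classes
  lp <- matrix(rep(log(params$priors), each = nrow(X)), nrow(X), length(lv))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    for (k in seq_along(lv)) {
      m <- params$means[k, j]; v <- params$vars[k, j]
      lp[, k] <- lp[, k] - 0.5 * log(2 * pi * v) - (x - m)^2 / (2 * v)
    }
  }
  colnames(lp) <- lv
  lp
}

logPostToProb <- function(lp) {
  mx <- apply(lp, 1, max)
  p <- exp(lp - mx)
  p / rowSums(p)
}

#' Fit the Gaussian Naive Bayes activity model
#'
#' Class-conditional Gaussian mean/variance per selected feature plus class
#' priors equal to the class frequencies. Each class must contribute at least
#' two windows so variances are estimable.
#'
#' @param table feature table from [buildFeatureTable()] (extra columns such
#'   as `window_start_s` are ignored).
#' @param labels factor/character of per-window activity labels.
#' @param features character vector of feature names to use (e.g. from
#'   [selectFeatures()]); default all schema features present in `table`.
#' @param varFloorFrac variance floor as a fraction of each feature's pooled
#'   variance (default 1e-6).
#' @return an [ActivityModel-class].
#' @export
fitActivity <- function(table, labels, features = NULL, varFloorFrac = 1e-6) {
  y <- factor(labels, levels = intersect(ACTIVITY_CLASSES, unique(as.character(labels))))
  if (nlevels(y) < 2) stop("at least two classes are required")
  if (any(table(y) < 2)) stop("every class needs at least 2 windows")
  if (is.null(features))
    features <- setdiff(names(table), c("window_start_s", "subject", "bin", "window"))
  miss <- setdiff(features, names(table))
  if (length(miss)) stop("missing feature column: ", paste(miss, collapse = ", "))
  X <- as.matrix(table[, features, drop = FALSE])
  p <- nbParams(X, y, varFloorFrac)
  new("ActivityModel", features = features, classes = p$classes,
      means = p$means, vars = p$vars, priors = p$priors,
      varFloorFrac = varFloorFrac)
}

#' Predict activity classes and posteriors
#'
#' Posteriors follow Bayes' rule under conditional feature independence;
#' the label is the posterior argmax with ties broken by the model's fixed
#' class order.
#'
#' @param model an [ActivityModel-class].
#' @param table feature table containing the model's selected features.
#' @return list with `posterior` (rows sum to 1, one column per class) and
#'   `labels` (factor).
#' @export
predictActivity <- function(model, table) {
  miss <- setdiff(model@features, names(table))
  if (length(miss)) stop("missing feature column: ", paste(miss, collapse = ", "))
  X <- as.matrix(table[, model@features, drop = FALSE])
  params <- list(means = model@means, vars = model@vars,
                 priors = model@priors, classes = model@classes)
  lp <- nbLogPosterior(params, X)
  post <- logPostToProb(lp)
  lab <- factor(model@classes[max.col(lp, ties.method = "first")],
                levels = model@classes)
  list(posterior = post, labels = lab)
}

# Deterministic per-(subject,class) row cap used to keep wrapper selection
# tractable: keeps an evenly spaced subset of each group's rows.
capRows <- function(y, subj, cap) {
  if (!is.finite(cap)) return(seq_along(y))
  keep <- unlist(lapply(split(seq_along(y), list(subj, y), drop = TRUE),
                        function(ix) {
                          if (length(ix) <= cap) return(ix)
                          ix[unique(round(seq(1, length(ix), length.out = cap)))]
                        }), use.names = FALSE)
  sort(keep)
}

#' Greedy wrapper feature selection for the activity classifier
#'
#' Forward selection maximizing leave-one-subject-out Naive Bayes accuracy:
#' at each round the candidate feature giving the largest LOSO accuracy gain
#' is added; selection stops when no candidate improves accuracy or `maxK`
#' features are selected. Ties are broken by schema order, so the procedure
#' is deterministic. Because the Naive Bayes log-posterior is additive over
#' features, each candidate is scored by adding its cached per-fold
#' log-density matrix to the running log-posterior, which makes the wrapper
#' linear rather than quadratic in the feature count.
#'
#' @param table feature table.
#' @param labels per-window labels (>= 2 classes).
#' @param subjects per-window subject identifiers (the LOSO unit).
#' @param maxK maximum subset size (default 20).
#' @param perGroupCap cap on rows per subject-class group used during
#'   selection (evenly spaced, deterministic); `Inf` disables.
#' @param varFloorFrac variance floor fraction.
#' @return character vector of selected feature names, with attribute
#'   `trace` (accuracy after each addition).
#' @export
selectFeatures <- function(table, labels, subjects, maxK = 20,
                           perGroupCap = 120, varFloorFrac = 1e-6) {
  y <- factor(labels, levels = intersect(ACTIVITY_CLASSES, unique(as.character(labels))))
  if (nlevels(y) < 2) stop("at least two classes are required for selection")
  feats <- setdiff(names(table), c("window_start_s", "subject", "bin", "window"))
  subj <- factor(subjects)
  keep <- capRows(y, subj, perGroupCap)
  X <- as.matrix(table[keep, feats, drop = FALSE])
  y <- droplevels(y[keep]); subj <- droplevels(subj[keep])
  n <- nrow(X); lv <- levels(y); nc <- length(lv); nf <- ncol(X)
  folds <- levels(subj)
  # cached per-class log densities of each row under its fold's model
  LD <- lapply(seq_len(nc), function(k) matrix(0, n, nf))
  logprior <- matrix(0, n, nc)
  for (s in folds) {
    te <- which(subj == s); tr <- which(subj != s)
    ytr <- y[tr]
    cnt <- tabulate(as.integer(ytr), nbins = nc)
    # classes absent from a fold's training set get zero prior there
    present <- cnt >= 2
    Xtr <- X[tr, , drop = FALSE]
    S1 <- rowsum(Xtr, factor(ytr, levels = lv))
    S2 <- rowsum(Xtr^2, factor(ytr, levels = lv))
    means <- S1 / pmax(cnt, 1)
    vars <- (S2 - cnt * means^2) / pmax(cnt - 1, 1)
    mu <- colMeans(Xtr)
    pooled <- (colSums(Xtr^2) - length(tr) * mu^2) / (length(tr) - 1)
    floorv <- pmax(varFloorFrac * pooled, 1e-12)
    vars <- pmax(vars, rep(floorv, each = nc))
    for (k in seq_len(nc)) {
      if (!present[k]) { LD[[k]][te, ] <- 0; next }
      M <- rep(means[k, ], each = length(te))
      V <- rep(vars[k, ], each = length(te))
      LD[[k]][te, ] <- -0.5 * log(2 * pi * V) - (X[te, , drop = FALSE] - M)^2 / (2 * V)
    }
    lpri <- ifelse(present, log(pmax(cnt, 1) / length(tr)), -Inf)
    logprior[te, ] <- rep(lpri, each = length(te))
  }
  yi <- as.integer(y)
  sel <- integer(0)
  B <- logprior
  best <- 0
  trace <- numeric(0)
  while (length(sel) < min(maxK, nf)) {
    cand <- setdiff(seq_len(nf), sel)
    accs <- vapply(cand, function(f) {
      S <- B
      for (k in seq_len(nc)) S[, k] <- S[, k] + LD[[k]][, f]
      mean(max.col(S, ties.method = "first") == yi)
    }, numeric(1))
    if (max(accs) <= best + 1e-12) break
    f <- cand[which.max(accs)]
    sel <- c(sel, f)
    for (k in seq_len(nc)) B[, k] <- B[, k] + LD[[k]][, f]
    best <- max(accs)
    trace <- c(trace, best)
  }
  if (length(sel) == 0) sel <- which.max(accs)  # degenerate: keep best single
  structure(feats[sel], trace = trace)
}

#' Leave-one-subject-out evaluation of the activity pipeline
#'
#' For each held-out subject, wrapper selection and Naive Bayes fitting run
#' on the remaining subjects only; predictions on the held-out subject's
#' windows are pooled into the overall accuracy and confusion matrix, so the
#' reported accuracy is free of within-subject leakage.
#'
#' @inheritParams selectFeatures
#' @return list with `accuracy`, `confusion` (true x predicted), `perSubject`
#'   data.frame, `selected` (list of per-fold feature sets) and `posterior`
#'   /`predicted` aligned with the input rows (out-of-sample for every row).
#' @export
evaluateLoso <- function(table, labels, subjects, maxK = 20, perGroupCap = 120,
                         varFloorFrac = 1e-6) {
  y <- factor(labels, levels = intersect(ACTIVITY_CLASSES, unique(as.character(labels))))
  subj <- factor(subjects)
  if (nlevels(subj) < 2) stop("leave-one-subject-out requires >= 2 subjects")
  classes <- levels(y)
  pred <- factor(rep(NA_character_, length(y)), levels = classes)
  post <- matrix(NA_real_, length(y), length(classes),
                 dimnames = list(NULL, classes))
  selected <- list()
  perSubject <- data.frame(subject = levels(subj), accuracy = NA_real_)
  for (s in levels(subj)) {
    te <- which(subj == s); tr <- which(subj != s)
    fs <- selectFeatures(table[tr, ], y[tr], subj[tr], maxK = maxK,
                         perGroupCap = perGroupCap, varFloorFrac = varFloorFrac)
    mod <- fitActivity(table[tr, ], droplevels(y[tr]), features = as.character(fs),
                       varFloorFrac = varFloorFrac)
    pr <- predictActivity(mod, table[te, ])
    pred[te] <- factor(as.character(pr$labels), levels = classes)
    post[te, mod@classes] <- pr$posterior
    post[te, is.na(colSums(post[te, , drop = FALSE]))] <- 0
    selected[[s]] <- as.character(fs)
    perSubject$accuracy[perSubject$subject == s] <- mean(pr$labels == y[te])
  }
  list(accuracy = mean(pred == y),
       confusion = table(true = y, predicted = pred),
       perSubject = perSubject, selected = selected,
       predicted = pred, posterior = post)
}

#' Persist / load an activity model as YAML
#'
#' Feature names, per-class means and variances, priors and the variance
#' floor, in a plain-text YAML file.
#'
#' @param model an [ActivityModel-class].
#' @param path YAML file path.
#' @return `writeActivityModel()` the path, invisibly;
#'   `readActivityModel()` the reconstructed model.
#' @export
writeActivityModel <- function(model, path) {
  yaml::write_yaml(list(
    features = model@features, classes = model@classes,
    means = lapply(seq_along(model@classes), function(k) as.numeric(model@means[k, ])),
    vars = lapply(seq_along(model@classes), function(k) as.numeric(model@vars[k, ])),
    priors = as.numeric(model@priors), varFloorFrac = model@varFloorFrac),
    path, precision = 15)
  invisible(path)
}

#' @rdname writeActivityModel
#' @export
readActivityModel <- function(path) {
  y <- yaml::read_yaml(path)
  k <- length(y$classes); f <- length(y$features)
  dims <- list(y$classes, y$features)
  new("ActivityModel", features = unlist(y$features), classes = unlist(y$classes),
      means = matrix(unlist(y$means), k, f, byrow = TRUE, dimnames = dims),
      vars = matrix(unlist(y$vars), k, f, byrow = TRUE, dimnames = dims),
      priors = setNames(unlist(y$priors), unlist(y$classes)),
      varFloorFrac = y$varFloorFrac)
}

#' Posture from gravity inclination of waist and shank
#'
#' For quasi-static windows the mean accelerometer vector approximates
#' gravity. Inclination is the angle between that vector and the proximal
#' (Y) axis. Rules: waist inclination > 60 degrees from vertical means
#' lying; waist < 45 degrees with shank > 45 degrees means sitting;
#' otherwise standing. Windows with gyroscope RMS above `staticGyroRms`
#' (deg/s) are not static; they return "standing" flagged low-confidence.
#'
#' @param waist,shank n x 9 (or n x 3 accelerometer-first) window matrices.
#' @param staticGyroRms quasi-static gate on gyro magnitude RMS (deg/s).
#' @return list with `posture` (one of standing/sitting/lying) and
#'   `lowConfidence` flag.
#' @export
detectPosture <- function(waist, shank, staticGyroRms = 20) {
  incl <- function(m) {
    g <- colMeans(m[, 1:3, drop = FALSE])
    acos(min(1, abs(g[2]) / max(sqrt(sum(g^2)), 1e-9))) * 180 / pi
  }
  gyroRms <- function(m) {
    if (ncol(m) >= 6) sqrt(mean(m[, 4:6]^2)) else 0
  }
  if (max(gyroRms(waist), gyroRms(shank)) > staticGyroRms)
    return(list(posture = "standing", lowConfidence = TRUE))
  wi <- incl(waist); si <- incl(shank)
  posture <- if (wi > 60) "lying"
  else if (wi < 45 && si > 45) "sitting"
  else "standing"
  list(posture = posture, lowConfidence = FALSE)
}
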