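# Validation statistics: scale binarization, ROC/Youden threshold selection,
# confusion metrics, Bland-Altman, correlations, day-to-day ICC, group
# comparison.

#' Binarize clinical annotations for one symptom rule
#'
#' Converts per-bin UPDRS/AIMS/diary annotations to positive / negative /
#' excluded following the clinical operating rules: positive when the item
#' rule is satisfied, negative at zero symptom presence, and excluded for
#' slight presence between the two (slight cases are ignored for accuracy
#' analysis). For the OFF rule, bins adjacent to a diary state transition
#' are additionally excluded to reduce transition-timing errors.
#'
#' Rules: `arm_brady` (items 23+24+25 > 4), `gait` (item 29 > 1; 1
#' excluded), `wrist_tremor` (item 20 wrist > 1; tremor-free everywhere for
#' negatives), `leg_tremor` (item 20 leg > 1), `dyskinesia` (AIMS total
#' > 4), `fog` (item 14 > 1), `off` (diary state).
#'
#' @param ann annotations data.frame (columns `updrs_*`, `aims_total`,
#'   `diary_state`; rows ordered in time within subject-day).
#' @param rule rule id.
#' @return data.frame `status` ("positive"/"negative"/"excluded") and
#'   `rule`.
#' @export
binarizeScale <- function(ann, rule) {
  n <- nrow(ann)
  status <- rep("excluded", n)
  pos <- neg <- rep(FALSE, n)
  switch(rule,
    arm_brady = {
      s <- ann$updrs_23 + ann$updrs_24 + ann$updrs_25
      pos <- s > 4; neg <- s == 0
    },
    gait = {
      pos <- ann$updrs_29 > 1; neg <- ann$updrs_29 == 0
    },
    wrist_tremor = {
      w <- pmax(ann$updrs_20_lw, ann$updrs_20_rw)
      allt <- pmax(w, ann$updrs_20_ll, ann$updrs_20_rl)
      pos <- w > 1; neg <- allt == 0
    },
    leg_tremor = {
      l <- pmax(ann$updrs_20_ll, ann$updrs_20_rl)
      allt <- pmax(l, ann$updrs_20_lw, ann$updrs_20_rw)
      pos <- l > 1; neg <- allt == 0
    },
    dyskinesia = {
      pos <- ann$aims_total > 4; neg <- ann$aims_total == 0
    },
    fog = {
      pos <- ann$updrs_14 > 1; neg <- ann$updrs_14 == 0
    },
    off = {
      st <- as.character(ann$diary_state)
      pos <- !is.na(st) & st == "OFF"
      neg <- !is.na(st) & st == "ON"
      # exclude bins adjacent to a state transition
      chg <- which(st[-1] != st[-n])
      drop <- unique(c(chg, chg + 1))
      pos[drop] <- neg[drop] <- FALSE
    },
    stop("unknown rule id: ", rule)
  )
  status[pos] <- "positive"; status[neg & !pos] <- "negative"
  data.frame(status = status, rule = rule)
}

#' ROC analysis with Youden threshold selection
#'
#' Enumerates every cutpoint of the score distribution (predict positive
#' when score > threshold), computes sensitivity/specificity along the
#' curve, and selects the threshold maximizing Youden's J = sensitivity +
#' specificity - 1; ties are resolved toward the lowest threshold. J is
#' invariant under strictly monotone transforms of the score.
#'
#' @param scores numeric device scores.
#' @param truth logical (or "positive"/"negative") ground truth.
#' @return list `curve` (threshold, tpr, fpr, J), `threshold`, `J`, `auc`,
#'   and `degenerate` (TRUE when scores carry no information).
#' @export
rocSelectThreshold <- function(scores, truth) {
  if (is.character(truth) || is.factor(truth)) truth <- as.character(truth) == "positive"
  ok <- !is.na(scores) & !is.na(truth)
  scores <- scores[ok]; truth <- truth[ok]
  nP <- sum(truth); nN <- sum(!truth)
  if (nP == 0 || nN == 0) stop("both classes are required for ROC analysis")
  thr <- sort(unique(c(-Inf, scores)))
  tpr <- vapply(thr, function(t) mean(scores[truth] > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!truth] > t), numeric(1))
  J <- tpr - fpr
  best <- which(J == max(J))[1]           # ties: lowest threshold wins
  # AUC via the rank (Mann-Whitney) identity
  auc <- (sum(rank(scores)[truth]) - nP * (nP + 1) / 2) / (nP * nN)
  list(curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr, J = J),
       threshold = thr[best], J = max(J), auc = auc,
       degenerate = max(J) <= 0)
}

#' Confusion-matrix metrics
#'
#' Accuracy, specificity and sensitivity from TP/FN/FP/TN counts. Exact
#' values are reported alongside display values rounded half-up to two
#' decimals; a metric below 1 is never displayed as 1.00 (it caps at 0.99),
#' matching the reporting convention that an imperfect classifier is not
#' printed as perfect. Empty margins give `NA` (undefined) metrics.
#'
#' @param tp,fn,fp,tn non-negative counts, total > 0.
#' @return list `counts`, `accuracy`, `specificity`, `sensitivity` (exact)
#'   and `display` (2-decimal values).
#' @export
confusionMetrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  acc <- (tp + tn) / (tp + fn + fp + tn)
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  disp <- function(x) {
    if (is.na(x)) return(NA_real_)
    r <- roundHalfUp(x, 2)
    if (x < 1 && r >= 1) 0.99 else r
  }
  list(counts = c(TP = tp, FN = fn, FP = fp, TN = tn),
       accuracy = acc, specificity = spec, sensitivity = sens,
       display = c(accuracy = disp(acc), specificity = disp(spec),
                   sensitivity = disp(sens)))
}

#' Bland-Altman agreement analysis
#'
#' Differences d = a - b: bias (mean), SD (n-1 denominator), the
#' reproducibility coefficient RPC = 1.96 SD, limits of agreement, the
#' coefficient of variation CV = SD / mean of the pair means x 100, and the
#' standard error of the differences.
#'
#' @param a,b paired measurements (>= 2 pairs).
#' @return list `bias, sd, rpc, loa, cv, sse, n`.
#' @export
blandAltman <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- a - b
  s <- sd(d)
  mm <- mean((a + b) / 2)
  list(bias = mean(d), sd = s, rpc = 1.96 * s,
       loa = c(lower = mean(d) - 1.96 * s, upper = mean(d) + 1.96 * s),
       cv = if (mm != 0) s / mm * 100 else NA_real_,
       sse = s / sqrt(length(d)), n = length(d))
}

#' Pearson and Spearman correlation of paired measures
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs, non-constant).
#' @return list `r`, `r2`, `rho`; `NA`s with a constant series.
#' @export
correlationStats <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, r2 = NA_real_, rho = NA_real_))
  r <- cor(x, y)
  list(r = r, r2 = r^2, rho = cor(x, y, method = "spearman"))
}

#' Day-to-day repeatability of per-day symptom summaries
#'
#' All within-subject unordered day pairs are formed; reported are the
#' squared Pearson correlation over those pairs (one common reading of a
#' day-to-day "ICC (r^2)") and the classical two-way random-effects
#' single-measure ICC(2,1) from the subject x day ANOVA, labeled
#' separately. ICC(2,1) uses subjects with the modal day count (extra days
#' dropped) so the two-way layout is balanced.
#'
#' @param df data.frame with `subject`, `day`, `value`.
#' @return list `pairs_r2`, `pairs_rho`, `icc21`, `nPairs`.
#' @export
dayToDayIcc <- function(df) {
  sp <- split(df, df$subject)
  p1 <- c(); p2 <- c()
  for (s in sp) {
    s <- s[order(s$day), ]
    if (nrow(s) < 2) next
    cmb <- utils::combn(nrow(s), 2)
    p1 <- c(p1, s$value[cmb[1, ]])
    p2 <- c(p2, s$value[cmb[2, ]])
  }
  if (length(p1) < 2) stop("need >= 2 days for >= 2 subjects")
  pr <- if (sd(p1) > 0 && sd(p2) > 0) cor(p1, p2) else NA_real_
  rho <- if (!is.na(pr)) cor(p1, p2, method = "spearman") else NA_real_
  # balanced two-way layout for ICC(2,1)
  cnt <- vapply(sp, nrow, integer(1))
  kk <- as.integer(names(sort(table(cnt[cnt >= 2]), decreasing = TRUE))[1])
  use <- sp[cnt >= kk]
  M <- t(vapply(use, function(s) s$value[order(s$day)][seq_len(kk)], numeric(kk)))
  n <- nrow(M); k <- ncol(M)
  icc <- NA_real_
  if (n >= 2 && k >= 2) {
    mu <- mean(M)
    MSR <- k * sum((rowMeans(M) - mu)^2) / (n - 1)
    MSC <- n * sum((colMeans(M) - mu)^2) / (k - 1)
    SSE <- sum((M - outer(rowMeans(M), colMeans(M), "+") + mu)^2)
    MSE <- SSE / ((n - 1) * (k - 1))
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  }
  list(pairs_r2 = pr^2, pairs_rho = rho, icc21 = icc, nPairs = length(p1))
}

#' Pairwise group comparison with box-plot summaries
#'
#' Welch t-tests for every group pair with the conventional significance
#' star bands (ns, *, **, ***, ****), plus per-group box statistics:
#' quartiles, whiskers extending to the furthest point within 1.5 IQR of
#' the box, and the outliers beyond.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @return list `tests` (group1, group2, p, stars), `boxes` (per group).
#' @export
groupCompare <- function(values, groups) {
  g <- factor(groups)
  lv <- levels(g)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("skipping groups with < 2 values: ", paste(small, collapse = ", "))
    lv <- setdiff(lv, small)
  }
  starsOf <- function(p) {
    if (p <= 1e-4) "****" else if (p <= 1e-3) "***"
    else if (p <= 1e-2) "**" else if (p <= 0.05) "*" else "ns"
  }
  tests <- list()
  if (length(lv) >= 2) {
    cmb <- utils::combn(lv, 2)
    for (i in seq_len(ncol(cmb))) {
      a <- values[g == cmb[1, i]]; b <- values[g == cmb[2, i]]
      p <- t.test(a, b)$p.value
      tests[[i]] <- data.frame(group1 = cmb[1, i], group2 = cmb[2, i],
                               p = p, stars = starsOf(p))
    }
  }
  boxes <- lapply(lv, function(l) {
    x <- values[g == l]
    q <- quantile(x, c(0.25, 0.5, 0.75))
    iqr <- q[3] - q[1]
    inl <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
    list(group = l, q1 = unname(q[1]), median = unname(q[2]),
         q3 = unname(q[3]), whiskers = range(inl),
         outliers = x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr])
  })
  names(boxes) <- lv
  list(tests = if (length(tests)) do.call(rbind, tests) else NULL,
       boxes = boxes)
}
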