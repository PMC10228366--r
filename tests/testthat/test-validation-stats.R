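test_that("confusion metrics reproduce the printed device-vs-expert table rows", {
  # printed counts -> printed accuracy/specificity/sensitivity (2 decimals)
  rows <- list(
    arm_brady = list(c(208, 41, 137, 781), c(0.85, 0.85, 0.84)),
    wrist_tremor = list(c(90, 17, 2, 2858), c(0.99, 0.99, 0.84)),
    leg_tremor = list(c(28, 2, 1, 1440), c(0.99, 0.99, 0.93)),
    dyskinesia = list(c(68, 15, 9, 1607), c(0.99, 0.99, 0.82)),
    off = list(c(29, 5, 18, 571), c(0.96, 0.97, 0.85)),
    fog = list(c(10, 2, 1, 61), c(0.96, 0.98, 0.83)))
  for (nm in names(rows)) {
    cm <- do.call(confusionMetrics, as.list(rows[[nm]][[1]]))
    expect_equal(unname(cm$display), rows[[nm]][[2]], label = nm)
  }
  # identities hold exactly
  cm <- confusionMetrics(208, 41, 137, 781)
  expect_equal(cm$accuracy, (208 + 781) / (208 + 41 + 137 + 781))
  expect_equal(cm$specificity, 781 / (781 + 137))
  expect_equal(cm$sensitivity, 208 / (208 + 41))
  # empty positive margin: sensitivity undefined, accuracy 1
  cm2 <- confusionMetrics(0, 0, 0, 10)
  expect_equal(cm2$accuracy, 1)
  expect_true(is.na(cm2$sensitivity))
})

test_that("ROC threshold selection maximizes Youden's J and matches brute force", {
  sc <- c(0.1, 0.2, 0.8, 0.9); tr <- c(FALSE, FALSE, TRUE, TRUE)
  r <- rocSelectThreshold(sc, tr)
  expect_equal(r$J, 1)
  expect_gt(r$threshold, 0.2 - 1e-12)
  expect_lte(r$threshold, 0.8)

  # brute-force oracle on random scores
  set.seed(11)
  for (i in 1:5) {
    sc <- runif(40); tr <- runif(40) < 0.4
    if (!any(tr) || all(tr)) next
    r <- rocSelectThreshold(sc, tr)
    Jof <- function(t) mean(sc[tr] > t) - mean(sc[!tr] > t)
    bruteJ <- max(vapply(c(-Inf, sc), Jof, numeric(1)))
    expect_equal(r$J, bruteJ, tolerance = 1e-12)
    # J invariant under strictly monotone transform
    r2 <- rocSelectThreshold(exp(3 * sc), tr)
    expect_equal(r2$J, r$J, tolerance = 1e-12)
  }

  # labels independent of scores: J near 0
  set.seed(12)
  sc <- runif(2000); tr <- runif(2000) < 0.5
  expect_lt(rocSelectThreshold(sc, tr)$J, 0.1)

  # degenerate: constant scores
  rd <- rocSelectThreshold(rep(1, 10), c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_true(rd$degenerate)
  expect_equal(rd$J, 0)
  expect_error(rocSelectThreshold(1:5, rep(TRUE, 5)), "both classes")
})

test_that("ROC agrees with an independent package implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- c(rnorm(60, 0), rnorm(40, 1.2)); tr <- rep(c(FALSE, TRUE), c(60, 40))
  r <- rocSelectThreshold(sc, tr)
  pr <- pROC::roc(tr, sc, quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  co <- pROC::coords(pr, "best", best.method = "youden", transpose = FALSE)
  bestJ <- max(co$sensitivity + co$specificity - 1)
  expect_equal(r$J, bestJ, tolerance = 1e-9)
})

test_that("Bland-Altman statistics obey their closed forms", {
  ba <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$bias, 0); expect_equal(ba$rpc, 0)

  ba2 <- blandAltman(c(1, 0), c(0, 1))  # differences +1, -1
  expect_equal(ba2$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(ba2$rpc, 1.96 * sqrt(2), tolerance = 1e-12)

  set.seed(14)
  a <- rnorm(50); b <- rnorm(50)
  ba3 <- blandAltman(a, b); ba4 <- blandAltman(a + 5, b)
  expect_equal(ba4$bias, ba3$bias + 5, tolerance = 1e-12)
  expect_equal(ba4$rpc, ba3$rpc, tolerance = 1e-12)
  expect_equal(ba3$rpc, 1.96 * sd(a - b), tolerance = 1e-12)
  expect_equal(ba3$sse, sd(a - b) / sqrt(50), tolerance = 1e-12)
  expect_error(blandAltman(1, 1), "2 pairs")
})

test_that("correlations match textbook estimators, Spearman captures monotone nonlinearity", {
  x <- 1:10
  cs <- correlationStats(x, 2 * x)
  expect_equal(cs$r, 1); expect_equal(cs$rho, 1)

  x <- -2:2
  cs2 <- correlationStats(x, x^3)
  expect_equal(cs2$rho, 1)
  expect_lt(cs2$r, 1)

  set.seed(15)
  a <- rnorm(30); b <- rnorm(30)
  cs3 <- correlationStats(a, b)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cs3$r, num / den, tolerance = 1e-12)
  expect_equal(cs3$r2, cs3$r^2)
  expect_true(is.na(correlationStats(rep(1, 5), 1:5)$r))
})

test_that("day-to-day ICC: identical days give 1, noise-dominated days give ~0, pair counts are right", {
  df <- data.frame(subject = rep(1:4, each = 3), day = rep(1:3, 4),
                   value = rep(c(1, 5, 9, 13), each = 3))
  r <- dayToDayIcc(df)
  expect_equal(r$pairs_r2, 1, tolerance = 1e-12)
  expect_equal(r$icc21, 1, tolerance = 1e-12)
  expect_equal(r$nPairs, 3 * 4)  # C(3,2) x 4 subjects

  set.seed(16)
  df2 <- data.frame(subject = rep(1:20, each = 2), day = rep(1:2, 20))
  df2$value <- 0.01 * df2$subject + rnorm(40, sd = 10)  # noise >> subject spread
  r2 <- dayToDayIcc(df2)
  expect_lt(abs(r2$icc21), 0.35)
  expect_lt(r2$pairs_r2, 0.3)

  expect_error(dayToDayIcc(data.frame(subject = 1:3, day = 1, value = 1:3)),
               ">= 2 days")
})

test_that("group comparison produces Welch p-values, star bands, and 1.5 IQR box partitions", {
  set.seed(17)
  gA <- rnorm(50); gB <- rnorm(50)
  res <- groupCompare(c(gA, gB), rep(c("A", "B"), each = 50))
  expect_equal(res$tests$p, t.test(gA, gB)$p.value, tolerance = 1e-12)

  gC <- rnorm(50, 5)
  res2 <- groupCompare(c(gA, gC), rep(c("A", "C"), each = 50))
  expect_equal(res2$tests$stars, "****")

  # identical groups: ns
  res3 <- groupCompare(c(gA, gA), rep(c("A", "B"), each = 50))
  expect_equal(res3$tests$stars, "ns")

  # whisker/outlier partition matches direct computation
  x <- c(rnorm(40), 8, -9)
  res4 <- groupCompare(x, rep("A", 42))
  q <- quantile(x, c(0.25, 0.75)); iqr <- diff(q)
  outliers <- x[x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr]
  expect_setequal(res4$boxes$A$outliers, outliers)
  expect_equal(res4$boxes$A$whiskers,
               range(x[x >= q[1] - 1.5 * iqr & x <= q[2] + 1.5 * iqr]))
  expect_warning(groupCompare(c(1, 2, 3), c("A", "A", "B")), "skipping")
})

test_that("annotation binarization applies rules, slight-case and transition exclusions", {
  ann <- data.frame(updrs_23 = c(2, 0, 1), updrs_24 = c(2, 0, 1),
                    updrs_25 = c(1, 0, 1))
  st <- binarizeScale(ann, "arm_brady")$status
  expect_equal(st, c("positive", "negative", "excluded"))

  ann2 <- data.frame(updrs_29 = c(0, 1, 2))
  expect_equal(binarizeScale(ann2, "gait")$status,
               c("negative", "excluded", "positive"))

  ann3 <- data.frame(updrs_20_lw = c(2, 1, 0, 0), updrs_20_rw = 0,
                     updrs_20_ll = c(0, 0, 2, 0), updrs_20_rl = 0)
  expect_equal(binarizeScale(ann3, "wrist_tremor")$status,
               c("positive", "excluded", "excluded", "negative"))

  ann4 <- data.frame(diary_state = c("ON", "ON", "OFF", "OFF", "ON"))
  st4 <- binarizeScale(ann4, "off")$status
  expect_equal(st4, c("negative", "excluded", "excluded", "excluded", "excluded"))
  expect_error(binarizeScale(ann4, "nope"), "unknown rule")
})
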