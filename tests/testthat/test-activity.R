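# Gaussian NB activity classifier: parameters, posteriors, wrapper
# selection, LOSO evaluation, posture.

makeToyTable <- function(n = 200, seed = 21, informative = TRUE) {
  set.seed(seed)
  y <- factor(rep(c("Walking", "Resting"), each = n / 2),
              levels = c("Walking", "Resting"))
  X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  names(X) <- paste0("f", 1:10)
  if (informative) X$f3 <- ifelse(y == "Walking", 5, -5) + rnorm(n, 0, 0.1)
  list(X = X, y = y, subj = rep(sprintf("S%d", 1:4), length.out = n))
}

test_that("NB parameters equal closed-form sample statistics and priors are class frequencies", {
  toy <- makeToyTable()
  mod <- fitActivity(toy$X, toy$y)
  expect_equal(unname(modelPriors(mod)), c(0.5, 0.5))
  expect_equal(mod@means["Walking", "f3"],
               mean(toy$X$f3[toy$y == "Walking"]), tolerance = 1e-12)
  expect_equal(mod@vars["Resting", "f1"],
               var(toy$X$f1[toy$y == "Resting"]), tolerance = 1e-12)
  # constant-within-class feature hits the variance floor, stays positive
  X2 <- toy$X; X2$f1 <- ifelse(toy$y == "Walking", 1, 2)
  mod2 <- fitActivity(X2, toy$y)
  expect_gt(min(mod2@vars[, "f1"]), 0)
  expect_equal(mod2@means["Walking", "f1"], 1)
  expect_error(fitActivity(toy$X, factor(rep("Walking", 200))), "two classes")
})

test_that("posteriors follow Bayes rule: symmetry, prior dominance, brute-force oracle, scale covariance", {
  # two symmetric unit-variance classes at +-1, x = 0 -> (0.5, 0.5)
  mod <- new("ActivityModel", features = "f", classes = c("Walking", "Resting"),
             means = matrix(c(1, -1), 2, 1, dimnames = list(NULL, "f")),
             vars = matrix(1, 2, 1), priors = c(Walking = 0.5, Resting = 0.5),
             varFloorFrac = 1e-6)
  pr <- predictActivity(mod, data.frame(f = 0))
  expect_equal(as.numeric(pr$posterior), c(0.5, 0.5), tolerance = 1e-12)

  # prior 1 forces the class
  mod2 <- mod; mod2@priors <- c(Walking = 1, Resting = 0)
  pr2 <- predictActivity(mod2, data.frame(f = c(-5, 0, 5)))
  expect_true(all(pr2$labels == "Walking"))

  # brute-force product-of-densities oracle on 3 features
  toy <- makeToyTable(seed = 22)
  mod3 <- fitActivity(toy$X[, 1:3], toy$y)
  x <- toy$X[7, 1:3]
  pr3 <- predictActivity(mod3, x)
  dens <- vapply(1:2, function(k) {
    prod(dnorm(as.numeric(x), mod3@means[k, ], sqrt(mod3@vars[k, ]))) *
      mod3@priors[k]
  }, numeric(1))
  expect_equal(as.numeric(pr3$posterior), dens / sum(dens), tolerance = 1e-9)
  expect_equal(rowSums(pr3$posterior), 1, ignore_attr = TRUE, tolerance = 1e-9)

  # consistent rescaling of a feature and its parameters leaves posteriors unchanged
  X4 <- toy$X[, 1:3]; X4$f1 <- X4$f1 * 10
  mod4 <- fitActivity(X4, toy$y)
  pr4 <- predictActivity(mod4, transform(toy$X[7, 1:3], f1 = f1 * 10))
  expect_equal(as.numeric(pr4$posterior), as.numeric(pr3$posterior),
               tolerance = 1e-9)
  expect_error(predictActivity(mod3, toy$X[, 1:2]), "missing feature")
})

test_that("wrapper selection finds the separating feature first and respects max_k", {
  toy <- makeToyTable()
  sel <- selectFeatures(toy$X, toy$y, toy$subj, maxK = 5)
  expect_equal(as.character(sel)[1], "f3")

  sel1 <- selectFeatures(toy$X, toy$y, toy$subj, maxK = 1)
  expect_length(as.character(sel1), 1)

  # pure-noise features: accuracy stays near chance and the subset stays small
  toy2 <- makeToyTable(seed = 23, informative = FALSE)
  sel2 <- selectFeatures(toy2$X, toy2$y, toy2$subj, maxK = 4)
  expect_lte(length(as.character(sel2)), 4)
  tr <- attr(sel2, "trace")
  expect_lt(max(tr), 0.75)  # n=200 noise: nowhere near separation

  # adding a duplicated column does not change selection-driven labels
  X3 <- toy$X; X3$f3dup <- X3$f3
  sel3 <- selectFeatures(X3, toy$y, toy$subj, maxK = 5)
  mA <- fitActivity(toy$X, toy$y, as.character(sel))
  mB <- fitActivity(X3, toy$y, as.character(sel3))
  expect_equal(as.character(predictActivity(mB, X3)$labels),
               as.character(predictActivity(mA, toy$X)$labels))
})

test_that("LOSO evaluation is leakage-free and matches chance on label-free data", {
  toy <- makeToyTable(n = 400)
  res <- evaluateLoso(toy$X, toy$y, toy$subj, maxK = 3)
  expect_equal(res$accuracy, 1, tolerance = 0.01)  # noiseless separating feature

  set.seed(24)
  n <- 500
  y <- factor(sample(c("Walking", "Resting", "Tremor", "Dyskinetic", "Other"),
                     n, replace = TRUE))
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  subj <- rep(sprintf("S%d", 1:5), length.out = n)
  res2 <- evaluateLoso(X, y, subj, maxK = 3)
  expect_lt(abs(res2$accuracy - 0.2), 0.1)  # 5 balanced classes: chance
  expect_error(evaluateLoso(X, y, rep("S1", n)), ">= 2 subjects")
})

test_that("NB posteriors agree with an independent package implementation", {
  skip_if_not_installed("e1071")
  # noise-only features keep densities away from underflow in either code path
  toy <- makeToyTable(seed = 25, informative = FALSE)
  mod <- fitActivity(toy$X[, 1:4], toy$y, varFloorFrac = 0)
  nb <- e1071::naiveBayes(toy$X[, 1:4], toy$y)
  pe <- predict(nb, toy$X[1:20, 1:4], type = "raw", threshold = 0, eps = 0)
  po <- predictActivity(mod, toy$X[1:20, 1:4])$posterior
  expect_equal(unname(po[, levels(toy$y)]), unname(pe[, levels(toy$y)]),
               tolerance = 1e-6)
})

test_that("posture detection reads gravity inclination of waist and shank", {
  quiet <- function(gv_waist, gv_shank) {
    mk <- function(gv) cbind(matrix(rep(gv, each = 50), 50, 3),
                             matrix(rnorm(150, 0, 0.5), 50, 3))
    list(waist = mk(gv_waist), shank = mk(gv_shank))
  }
  s <- quiet(c(0, 1, 0), c(0, 1, 0))   # both vertical
  expect_equal(detectPosture(s$waist, s$shank)$posture, "standing")
  s <- quiet(c(1, 0, 0), c(1, 0, 0))   # waist horizontal
  expect_equal(detectPosture(s$waist, s$shank)$posture, "lying")
  s <- quiet(c(0, 1, 0), c(1, 0, 0))   # waist up, shank horizontal
  expect_equal(detectPosture(s$waist, s$shank)$posture, "sitting")
  # non-static window falls back to standing, flagged
  mov <- cbind(matrix(0, 50, 3), matrix(100, 50, 3))
  out <- detectPosture(mov, mov)
  expect_equal(out$posture, "standing")
  expect_true(out$lowConfidence)
})
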