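test_that("LDA places the boundary midway between symmetric class means", {
  X <- matrix(c(-1.2, -1.0, -0.8, 0.8, 1.0, 1.2), ncol = 1)
  y <- rep(c("A", "B"), each = 3)
  m <- trainLDA(X, y)
  expect_equal(m$bias, 0)
  expect_equal(m$classes, c("A", "B"))
  # mean difference A - B is negative, so positive scores (class A) need x < 0
  expect_gt(sum(m$weights * -1) + m$bias, 0)
})

test_that("duplicating every trial leaves the decision sign pattern unchanged", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c("A", "B"), 10)
  m1 <- trainLDA(X, y)
  m2 <- trainLDA(rbind(X, X), c(y, y))
  # duplication rescales the pooled covariance by (n-2)/(2n-2), so weights
  # and bias scale together and every decision is preserved
  s1 <- X %*% m1$weights + m1$bias
  s2 <- X %*% m2$weights + m2$bias
  expect_identical(sign(s1), sign(s2))
  expect_equal(m1$weights / m2$weights, rep(m1$bias / m2$bias, 2),
               tolerance = 1e-9)
})

test_that("LDA assignments agree with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(9)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 1.5), ncol = 2))
  y <- rep(c("A", "B"), each = 30)
  m <- trainLDA(X, y)
  mine <- ifelse(X %*% m$weights + m$bias > 0, "A", "B")
  ref <- as.character(predict(MASS::lda(X, grouping = y))$class)
  expect_equal(as.character(mine), ref)
})

test_that("LDA survives singular covariance via ridge stabilization", {
  X <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), 4, 2)  # perfectly collinear features
  y <- c("A", "A", "B", "B")
  expect_no_error(m <- trainLDA(X, y))
  expect_true(all(is.finite(m$weights)))
})

test_that("calibration reaches perfect LooCV accuracy on separable classes", {
  sess <- sineSession(rep(c(4, 1), each = 7), rep(c("A", "B"), each = 7),
                      noiseSd = 0.02, seed = 2)
  res <- calibrate(sess, list(pairDerivation()))
  expect_s4_class(res$classifier, "CalibratedClassifier")
  expect_equal(res$classifier@loocvMedianAccuracy, 1.0)
  expect_length(res$report$windowAccuracies, 8)
  expect_true(all(res$report$windowAccuracies >= 0 &
                    res$report$windowAccuracies <= 1))
})

test_that("the chosen window always has the highest median accuracy", {
  set.seed(17)
  for (rep in 1:3) {
    sess <- sineSession(rnorm(14, 2, 0.5), rep(c("A", "B"), 7),
                        noiseSd = 0.5, seed = 30 + rep)
    res <- calibrate(sess, list(pairDerivation()))
    expect_equal(res$classifier@loocvMedianAccuracy,
                 max(res$report$windowAccuracies))
  }
})

test_that("an all-window tie selects the earliest 0.5 s window", {
  # constant class-specific amplitude: all eight windows see identical stats
  sess <- sineSession(rep(c(4, 1), each = 6), rep(c("A", "B"), each = 6),
                      noiseSd = 0.01, seed = 4)
  res <- calibrate(sess, list(pairDerivation()))
  expect_equal(res$classifier@trainWindow, c(4, 4.5))
})

test_that("shuffled labels give near-chance LooCV accuracy at n = 60", {
  set.seed(123)
  sess <- sineSession(rnorm(60, 2, 0.3), sample(rep(c("A", "B"), 30)),
                      noiseSd = 0.5, seed = 60)
  res <- calibrate(sess, list(pairDerivation()))
  expect_lt(abs(res$classifier@loocvMedianAccuracy - 0.5), 0.1)
})

test_that("calibration is deterministic and defers on starved classes", {
  sess <- sineSession(rep(c(3, 1), each = 5), rep(c("A", "B"), each = 5),
                      noiseSd = 0.1, seed = 6)
  r1 <- calibrate(sess, list(pairDerivation()))
  r2 <- calibrate(sess, list(pairDerivation()))
  expect_identical(r1, r2)

  starved <- sineSession(c(3, 3, 1), c("A", "A", "B"), seed = 7)
  expect_error(calibrate(starved, list(pairDerivation())), "deferred")
})

test_that("automatic class selection evaluates all six pairs and matches brute force", {
  sess <- sineSession(rep(c(6, 3, 1.5, 0.7), each = 5),
                      rep(c("Feet", "Hand", "Math", "Word"), each = 5),
                      noiseSd = 0.1, seed = 10)
  res <- autoSelectClasses(sess, list(pairDerivation()))
  expect_equal(nrow(res$candidates), 6)

  # oracle: an external loop over the six pairs calling calibrate() and sorting
  classes <- c("Feet", "Hand", "Math", "Word")
  pairs <- combn(classes, 2)
  acc <- fish <- numeric(6)
  for (p in 1:6) {
    keep <- trialLabels(sess) %in% pairs[, p]
    sub <- epochedSession(epochData(sess)[keep, , , drop = FALSE],
                          trialLabels(sess)[keep], sessionTiming(sess),
                          channelLabels(sess))
    r <- calibrate(sub, list(pairDerivation()))
    acc[p] <- r$classifier@loocvMedianAccuracy
    fish[p] <- r$classifier@bestFeatureFisher
  }
  expect_equal(res$candidates$loocvMedianAccuracy, acc, tolerance = 1e-12)
  best <- which(acc == max(acc))
  best <- best[which.max(fish[best])]
  expect_equal(sort(res$pair), sort(pairs[, best]))
})

test_that("accuracy ties between pairs break toward higher Fisher separability", {
  # widely separated constant amplitudes: every pair is perfectly separable,
  # so the LooCV accuracies all tie at 1 and the Fisher tie-break decides
  amps <- c(Art = 2, Bee = 4, Cee = 0.3, Zed = 10)
  sess <- sineSession(rep(amps, each = 5), rep(names(amps), each = 5),
                      noiseSd = 0.005, seed = 12)
  res <- autoSelectClasses(sess, list(pairDerivation()))
  expect_true(all(res$candidates$loocvMedianAccuracy == 1))
  # independent computation of each pair's best-feature Fisher score
  feats <- computeFeatures(sess, list(pairDerivation()))
  lab <- trialLabels(sess)
  pairs <- combn(names(amps), 2)
  fish <- vapply(seq_len(ncol(pairs)), function(p) {
    keep <- lab %in% pairs[, p]
    selectBestBand(feats$values[keep, , , drop = FALSE], lab[keep], 64)$score
  }, 0)
  expect_equal(sort(res$pair), sort(pairs[, which.max(fish)]))
  expect_false(identical(sort(res$pair), c("Art", "Bee")))  # not just first pair
})
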