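test_that("epoch extraction aligns trials to the relax-period start", {
  tm <- trialTiming()
  fs <- tm@fs
  cont <- matrix(rnorm(2 * 13 * fs), 2, dimnames = list(c("A", "B"), NULL))
  # an event at t = 3 s starts its epoch at t = 0, so recording sample 769
  # (t = 3 s) must land at epoch sample 769
  cont["A", 769] <- 99

  s0 <- extractEpochs(cont, data.frame(onset = numeric(0), label = character(0)), tm)
  expect_equal(nTrials(s0), 0)

  s1 <- extractEpochs(cont, data.frame(onset = 3, label = "Hand"), tm)
  expect_equal(dim(epochData(s1)), c(1, 2, 2560))
  expect_equal(unname(epochData(s1)[1, 1, 769]), 99)
  expect_equal(trialLabels(s1), "Hand")

  # overlapping events are both extracted
  s2 <- extractEpochs(cont, data.frame(onset = c(3, 4), label = c("Hand", "Word")), tm)
  expect_equal(nTrials(s2), 2)
  expect_equal(unname(epochData(s2)[2, 1, 769 - fs]), 99)  # shifted by one second

  # truncated trial dropped with a warning
  expect_warning(
    s3 <- extractEpochs(cont, data.frame(onset = c(3, 10), label = c("A", "B")), tm),
    "dropped")
  expect_equal(nTrials(s3), 1)
})

test_that("amplitude criterion is a strict threshold", {
  expect_false(rejectAmplitude(matrix(0, 2, 100), 100))
  seg <- matrix(0, 2, 100); seg[1, 50] <- -150
  expect_true(rejectAmplitude(seg, 100))
  segEdge <- matrix(100, 2, 100)   # exactly at the limit: kept
  expect_false(rejectAmplitude(segEdge, 100))
  expect_true(rejectAmplitude(matrix(100.0001, 1, 10), 100))
})

test_that("statistical rejection finds a heavy-spiked trial via kurtosis", {
  set.seed(11)
  n <- 21
  segs <- array(rnorm(n * 1 * 512), c(n, 1, 512))
  spike <- numeric(512)
  spike[sample(512, 6)] <- 12            # sparse spikes: high kurtosis
  segs[21, 1, ] <- rnorm(512, sd = 0.5) + spike

  # independent check that trial 21 is the kurtosis outlier, by the raw formula
  kur <- apply(segs[, 1, ], 1, function(x) {
    m <- mean(x); mean((x - m)^4) / mean((x - m)^2)^2 - 3
  })
  expect_equal(which.max(kur), 21L)
  expect_gt((kur[21] - mean(kur)) / sd(kur), 3.5)

  expect_true(21 %in% rejectStatistical(segs, 3.5))
})

test_that("statistical rejection degenerate cases reject nothing", {
  flat <- array(rep(sin(1:128), each = 5), c(5, 1, 128))
  expect_length(rejectStatistical(flat, 3.5), 0)      # identical trials
  two <- array(rnorm(2 * 2 * 64), c(2, 2, 64))
  expect_length(rejectStatistical(two, 3.5), 0)       # fewer than 3 trials
})

test_that("iterative band-power rejection flags a gross power outlier", {
  # n must exceed ~15: in a sample of n the largest attainable |z| is
  # (n-1)/sqrt(n), so a lone outlier can mask itself in smaller groups
  fs <- 64
  set.seed(5)
  n <- 20
  t <- (0:511) / fs
  segs <- array(0, c(n, 1, 512))
  for (tr in 1:n)
    segs[tr, 1, ] <- sin(2 * pi * 11 * t + runif(1) * 6) + rnorm(512, sd = 0.1)
  segs[5, 1, ] <- 10 * segs[5, 1, ]   # 100x band power
  rej <- rejectBandpowerIterative(segs, defaultBands(), fs)
  expect_true(5 %in% rej)

  # idempotence: survivors form a fixed point
  surv <- setdiff(1:n, rej)
  expect_length(rejectBandpowerIterative(segs[surv, , , drop = FALSE],
                                         defaultBands(), fs), 0)

  # identical trials are never rejected
  same <- array(rep(segs[1, 1, ], each = 6), c(6, 1, 512))
  expect_length(rejectBandpowerIterative(same, defaultBands(), fs), 0)
})

test_that("full pipeline flags nothing on a small clean deterministic session", {
  # 12 trials: with n = 12 the largest attainable |z| is (n-1)/sqrt(n) < 3.5,
  # so only the amplitude phase could reject, and amplitudes stay below 100
  sess <- sineSession(rep(c(1, 2), 6), rep(c("A", "B"), 6), noiseSd = 0.05)
  out <- runOutlierPipeline(sess, rejectionConfig(), list(pairDerivation()))
  expect_equal(sum(artifactFlags(out)), 0)
  expect_identical(epochData(out), epochData(sess))  # signals untouched
})

test_that("full pipeline flags injected high-amplitude trials", {
  gen <- generateSession(smallSpec(seed = 3, runs = 4L, artifactRate = 0.1))
  g <- electrodeGrid(c("C3", "Cz", "C4", "Pz"), c(1, 1, 1, 2), c(1, 2, 3, 2))
  der <- parseDerivations(g, "C3-Cz")
  out <- runOutlierPipeline(gen$session, rejectionConfig(), der)
  injected <- which(gen$truth$artifactFlags)
  expect_gt(length(injected), 0)
  expect_true(all(injected %in% which(artifactFlags(out))))
  # every injected trial was caught by the amplitude phase
  log <- rejectionLog(out)
  for (tr in injected)
    expect_true("amplitude" %in% log$trials[[tr]]$phase)
})

test_that("condition-specific imagery screening flags only the drifting trial", {
  n <- 16
  amps <- rep(1, 2 * n)
  labels <- rep(c("A", "B"), each = n)
  gains <- rep(1, 2 * n)
  gains[3] <- 5   # trial 3 (class A): imagery power drifts grossly
  sess <- sineSession(amps, labels, noiseSd = 0.05, imageryGain = gains, seed = 8)
  out <- runOutlierPipeline(sess, rejectionConfig(), list(pairDerivation()))
  expect_true(artifactFlags(out)[3])
  expect_equal(which(artifactFlags(out)), 3L)
  log <- rejectionLog(out)$trials[[3]]
  expect_true(all(grepl("imagery", log$segment)))   # relax pooling unaffected
})

test_that("pipeline order and flag invariance under trial permutation", {
  sess <- sineSession(rep(c(1, 2), 10), rep(c("A", "B"), 10), noiseSd = 0.3,
                      seed = 21)
  cfg <- rejectionConfig()
  der <- list(pairDerivation())
  out1 <- runOutlierPipeline(sess, cfg, der)
  perm <- sample(seq_len(nTrials(sess)))
  sessP <- epochedSession(epochData(sess)[perm, , , drop = FALSE],
                          trialLabels(sess)[perm], sessionTiming(sess),
                          channelLabels(sess))
  out2 <- runOutlierPipeline(sessP, cfg, der)
  expect_identical(artifactFlags(out2), artifactFlags(out1)[perm])
})
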