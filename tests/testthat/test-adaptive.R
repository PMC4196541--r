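# deterministic two-class session: within-class trials are identical, so the
# prequential rejection statistics have zero spread and never fire
deterministicSession <- function(labels, ampA = 3, ampB = 1, fs = 64) {
  tm <- fastTiming(fs)
  nS <- round(tm@trialEnd * fs)
  t <- (seq_len(nS) - 1) / fs
  base <- sin(2 * pi * 11 * t)
  n <- length(labels)
  amps <- ifelse(labels == sort(unique(labels))[1], ampA, ampB)
  epochs <- array(0, c(n, 2, nS))
  for (tr in seq_len(n)) epochs[tr, 1, ] <- amps[tr] * base
  epochedSession(epochs, labels, tm, c("A", "B"))
}

miniCfg <- function(classes, fs = 64, ...) {
  adaptiveConfig("mini", list(pairDerivation()), classes,
                 timing = fastTiming(fs), ...)
}

test_that("the 7-TPC schedule calibrates after trial 14 and recalibrates after 28", {
  labels <- rep(c("L", "R"), 21)   # strictly alternating, 42 trials
  sess <- deterministicSession(labels)
  res <- runSession(sess, miniCfg(c("L", "R")))
  expect_true(res@calibrated)
  expect_equal(res@modelArrivals[1], 14L)
  expect_equal(res@modelArrivals[2], 28L)
  # 21 per class: initial at 7 TPC plus two full 7-TPC update rounds
  expect_length(res@models, 3)
  # trials before initial calibration carry no predictions
  expect_true(all(is.na(res@trialLog$modelVersion[1:14])))
  expect_true(all(res@trialLog$evaluated[15:42]))
})

test_that("a four-class round-robin stream calibrates after trial 28", {
  labels <- rep(c("Feet", "Hand", "Math", "Word"), 10)
  tm <- fastTiming(64)
  nS <- round(tm@trialEnd * 64)
  t <- (seq_len(nS) - 1) / 64
  amps <- c(Feet = 4, Hand = 2, Math = 1, Word = 0.5)
  epochs <- array(0, c(length(labels), 2, nS))
  for (tr in seq_along(labels))
    epochs[tr, 1, ] <- amps[labels[tr]] * sin(2 * pi * 11 * t)
  sess <- epochedSession(epochs, labels, tm, c("A", "B"))
  cfg <- adaptiveConfig("auto", list(pairDerivation()),
                        c("Feet", "Hand", "Math", "Word"), timing = tm)
  res <- runSession(sess, cfg)
  expect_equal(res@modelArrivals[1], 28L)
  expect_length(selectedPair(res), 2)
  # after pair selection only the selected pair's trials are evaluated
  ev <- res@trialLog[res@trialLog$evaluated, ]
  expect_true(all(ev$label %in% selectedPair(res)))
})

test_that("an all-artifact stream never calibrates and never predicts", {
  sess <- deterministicSession(rep(c("L", "R"), 8))
  art <- epochData(sess)
  art[, 1, 100] <- 500   # every trial violates the amplitude rule
  sessArt <- epochedSession(art, trialLabels(sess), sessionTiming(sess),
                            channelLabels(sess))
  res <- runSession(sessArt, miniCfg(c("L", "R")))
  expect_false(res@calibrated)
  expect_length(res@models, 0)
  expect_equal(nrow(res@predictions), 0)
  expect_true(all(res@trialLog$artifact[res@trialLog$inScope]))
})

test_that("trials outside the configured classes are skipped", {
  labels <- rep(c("L", "R", "X"), 10)
  sess <- deterministicSession(labels)
  res <- runSession(sess, miniCfg(c("L", "R")))
  expect_true(all(!res@trialLog$inScope[labels == "X"]))
  expect_true(res@calibrated)
})

test_that("no information leaks: models predate the trials they classify", {
  gen <- generateSession(smallSpec(seed = 5, runs = 6L,
    effects = list(list(class = "Hand", electrode = "Cz", band = 2, value = -0.5))))
  g <- electrodeGrid(c("C3", "Cz", "C4", "Pz"), c(1, 1, 1, 2), c(1, 2, 3, 2))
  cfg <- adaptiveConfig("mini", parseDerivations(g, "Cz-Pz"), c("Hand", "Word"),
                        timing = sessionTiming(gen$session))
  res <- runSession(gen$session, cfg)
  lg <- res@trialLog
  for (i in which(lg$evaluated))
    expect_lt(res@modelArrivals[lg$modelVersion[i]], i)
  expect_true(all(diff(res@modelArrivals) > 0))
})

test_that("identical input gives bit-identical results", {
  gen <- generateSession(smallSpec(seed = 6, runs = 4L,
    effects = list(list(class = "Hand", electrode = "Cz", band = 2, value = -0.5))))
  g <- electrodeGrid(c("C3", "Cz", "C4", "Pz"), c(1, 1, 1, 2), c(1, 2, 3, 2))
  cfg <- adaptiveConfig("mini", parseDerivations(g, "Cz-Pz"), c("Hand", "Word"),
                        timing = sessionTiming(gen$session))
  r1 <- runSession(gen$session, cfg)
  r2 <- runSession(gen$session, cfg)
  expect_identical(r1, r2)
})

test_that("the total-count update rule recalibrates more often", {
  labels <- rep(c("L", "R"), 18)
  sess <- deterministicSession(labels)
  perClass <- runSession(sess, miniCfg(c("L", "R")))
  total <- runSession(sess, miniCfg(c("L", "R"), updateRule = "total"))
  expect_gt(length(total@models), length(perClass@models))
})

test_that("mode/class mismatches are rejected before any computation", {
  expect_error(adaptiveConfig("smr", list(pairDerivation()), c("A", "B", "C", "D")),
               "two classes")
  expect_error(adaptiveConfig("auto", list(pairDerivation()), c("A", "B")),
               "four classes")
  expect_error(adaptiveConfig("mini", list(pairDerivation(), pairDerivation()),
                              c("A", "B")), "one bipolar")
  expect_error(adaptiveConfig("mini", list(pairDerivation()), c("A", "B"),
                              nInitTpc = 1), "nInitTpc")
})
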