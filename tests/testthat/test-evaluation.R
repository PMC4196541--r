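# build a minimal AdaptiveSessionResult with hand-written predictions
resultFixture <- function(predRows, labels, pair = c("A", "B"), fs = 64) {
  n <- length(labels)
  tm <- trialTiming(fs = fs)
  log <- data.frame(arrival = seq_len(n), label = labels, inScope = TRUE,
                    artifact = FALSE, modelVersion = 1L, evaluated = TRUE)
  clf <- new("CalibratedClassifier", classPair = pair,
             selectedFeatures = data.frame(derivation = "A-B", band = 1L),
             trainWindow = c(4, 4.5), weights = 1, bias = 0,
             loocvMedianAccuracy = 1, bestFeatureFisher = 1)
  new("AdaptiveSessionResult", trialLog = log, predictions = predRows,
      models = list(clf), modelArrivals = 0L, selectedPair = pair,
      calibrated = TRUE, timing = tm, validFrom = 1)
}

test_that("accuracy time courses match hand-computed fractions", {
  nS <- 640
  ones <- matrix(1L, 2, nS)                        # both predict class A always
  tcAll <- accuracyTimecourse(resultFixture(ones, c("A", "A")))
  expect_true(all(tcAll$accuracy == 1))
  expect_equal(tcAll$nTrials, 2)

  tcHalf <- accuracyTimecourse(resultFixture(ones, c("A", "B")))
  expect_true(all(tcHalf$accuracy == 0.5))

  # three-trial table with a prediction switch at sample 321 (t = 5 s)
  pr <- rbind(c(rep(1L, 320), rep(2L, 320)),
              rep(1L, nS),
              rep(2L, nS))
  tc3 <- accuracyTimecourse(resultFixture(pr, c("A", "A", "B")))
  expect_equal(unname(tc3$accuracy[tc3$times < 5][1]), 1)
  expect_equal(unname(tc3$accuracy[tc3$times >= 5][1]), 2 / 3)
  pr2 <- rbind(c(rep(1L, 320), rep(2L, 320)),
               rep(1L, nS),
               rep(1L, nS))
  tc4 <- accuracyTimecourse(resultFixture(pr2, c("A", "A", "B")))
  expect_equal(unname(tc4$accuracy[tc4$times == 0][1]), 2 / 3)
  expect_equal(unname(tc4$accuracy[tc4$times == 6][1]), 1 / 3)
})

test_that("warm-up timepoints are excluded from the accuracy curve", {
  nS <- 640
  pr <- matrix(1L, 2, nS)
  pr[, 1:64] <- NA
  tc <- accuracyTimecourse(resultFixture(pr, c("A", "A")))
  expect_equal(length(tc$accuracy), nS - 64)
  expect_gt(min(tc$times), 0.9)
})

test_that("median and peak accuracy summarize the 4-8 s window", {
  tc <- structure(list(times = seq(0, 10, by = 0.01),
                       accuracy = rep(0.8, 1001), nTrials = 10),
                  class = "AccuracyTimecourse")
  expect_equal(medianAccuracy(tc), 0.8)
  expect_equal(peakAccuracy(tc), 0.8)

  ramp <- tc
  ramp$accuracy <- 0.5 + 0.05 * ramp$times   # linear ramp, 0.7 -> 0.9 in window
  expect_equal(peakAccuracy(ramp), 0.5 + 0.05 * max(ramp$times[ramp$times < 8]))

  set.seed(2)
  for (i in 1:200) {
    tc$accuracy <- runif(1001)
    expect_gte(peakAccuracy(tc), medianAccuracy(tc))
  }
  expect_error(medianAccuracy(tc, c(20, 30)), "overlap")
})

test_that("exact binomial chance bounds match brute-force tail summation", {
  expect_equal(chanceLevel(60, 2, 0.01), 40 / 60)
  bruteBound <- function(n, p, alpha) {
    for (k in 0:n) {
      tail <- sum(vapply(k:n, function(j)
        choose(n, j) * p^j * (1 - p)^(n - j), 0))
      if (tail <= alpha) return(k / n)
    }
  }
  for (n in c(20, 60, 100))
    expect_equal(chanceLevel(n, 2, 0.01), bruteBound(n, 0.5, 0.01))
  expect_equal(chanceLevel(45, 5, 0.05), bruteBound(45, 0.2, 0.05))
  # alpha near 1 approaches the guessing rate
  expect_lt(chanceLevel(100, 4, 0.999) - 0.25, 0.02)
})

test_that("chance bounds are monotone in trials and significance", {
  ns <- c(10, 20, 40, 80, 160, 320)
  for (cl in c(2, 4)) {
    b <- vapply(ns, chanceLevel, 0, nClasses = cl, alpha = 0.01)
    expect_true(all(diff(b) <= 0))             # non-increasing in n
  }
  alphas <- c(0.1, 0.05, 0.01, 0.001)
  b <- vapply(alphas, function(a) chanceLevel(60, 2, a), 0)
  expect_true(all(diff(b) >= 0))               # stricter alpha, higher bound
})

test_that("greedy channel selection skips overlapping derivations", {
  g <- electrodeGrid(paste0("E", 1:6), rep(1, 6), 1:6)
  ders <- list(bipolarDerivation(g, "E1", "E3"),   # rank 1 (covers 1-3)
               bipolarDerivation(g, "E3", "E5"),   # rank 2, overlaps rank 1
               bipolarDerivation(g, "E4", "E6"),   # rank 3, overlaps rank 2
               bipolarDerivation(g, "E5", "E6"))   # rank 4, overlaps 2 and 3
  sweep <- data.frame(derivation = rep(vapply(ders, derivationLabel, ""), 2),
                      classA = "L", classB = "R",
                      medianAccuracy = rep(c(0.9, 0.8, 0.7, 0.6), 2))
  attr(sweep, "derivations") <- ders
  class(sweep) <- c("SweepResult", class(sweep))
  sel <- selectChannels(sweep, k = 2)
  expect_equal(vapply(sel$selected, derivationLabel, ""), c("E1-E3", "E4-E6"))
  expect_equal(sel$trace$action[2], "skipped:overlap")
  # mutual non-overlap always holds
  for (i in seq_along(sel$selected))
    for (j in seq_along(sel$selected))
      if (i != j) expect_false(derivationsOverlap(sel$selected[[i]],
                                                  sel$selected[[j]]))
  expect_warning(selectChannels(sweep, k = 4), "non-overlapping")
})

test_that("class selection drops the weakest class and breaks ties by name", {
  g <- pairGrid()
  d <- pairDerivation(g)
  pairs <- combn(c("F", "H", "M", "N", "W"), 2)
  acc <- rep(0.9, ncol(pairs))
  acc[pairs[1, ] == "N" | pairs[2, ] == "N"] <- 0.5   # N at chance in every pair
  sweep <- data.frame(derivation = derivationLabel(d),
                      classA = pairs[1, ], classB = pairs[2, ],
                      medianAccuracy = acc)
  attr(sweep, "derivations") <- list(d)
  class(sweep) <- c("SweepResult", class(sweep))
  sel <- selectClasses(sweep, list(d), m = 4)
  expect_setequal(as.character(sel), c("F", "H", "M", "W"))

  flat <- sweep; flat$medianAccuracy <- 0.7
  expect_equal(as.character(selectClasses(flat, list(d), m = 4)),
               c("F", "H", "M", "N"))    # lexicographic tie rule
})

test_that("separability maps peak at the injected site and stay nonnegative", {
  gen <- generateSession(smallSpec(seed = 9, runs = 4L, tpcpr = 8L,
    effects = list(list(class = "Hand", electrode = "Cz", band = 2, value = -0.6),
                   list(class = "Hand", electrode = "Pz", band = 2, value = -0.6))))
  g <- electrodeGrid(c("C3", "Cz", "C4", "Pz"), c(1, 1, 1, 2), c(1, 2, 3, 2))
  ders <- parseDerivations(g, c("Cz-Pz", "C3-Cz"))
  map <- separabilityMap(gen$session, ders, rejection = NULL)
  expect_true(all(map >= 0))
  peak <- which(map == max(map), arr.ind = TRUE)
  expect_equal(unname(peak[1, "col"]), 2L)      # injected band
  expect_equal(rownames(map)[peak[1, "row"]], "Cz-Pz")

  nullGen <- generateSession(smallSpec(seed = 10, runs = 4L, tpcpr = 8L))
  nullMap <- separabilityMap(nullGen$session, ders, rejection = NULL)
  expect_lt(max(nullMap), 0.5)                  # no structure, near zero
  expect_error(separabilityMap(gen$session, ders, filter = "MTvsMT",
                               motorClasses = "Hand", rejection = NULL),
               "no class pair")
})
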