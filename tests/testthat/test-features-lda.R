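test_that("63-channel epoch sets yield 504-dimensional feature vectors", {
  fm <- extractIntervalMeans(cleanEpochs())
  expect_identical(ncol(values(fm)), 504L)
  expect_identical(length(channelLabels(fm)), 63L)
})

test_that("interval means reproduce constants and analytic ramp averages", {
  nT <- 140
  tMs <- seq(-200, 1190, by = 10)
  d <- array(0, dim = c(2, 2, nT))
  d[1, , ] <- 3.2                               # constant epoch
  d[2, 1, ] <- tMs; d[2, 2, ] <- tMs            # linear ramp in time
  ep <- toyEpochs(d, timeMs = tMs)
  fm <- extractIntervalMeans(ep, channels = c("ch1", "ch2"))
  expect_true(all(abs(values(fm)[1, ] - 3.2) < 1e-12))
  ivs <- list(c(100, 190), c(191, 300), c(301, 450), c(451, 560),
              c(561, 700), c(701, 850), c(851, 1000), c(1001, 1200))
  analytic <- vapply(ivs, function(iv)
    mean(tMs[tMs >= iv[1] & tMs <= iv[2]]), numeric(1L))
  expect_equal(unname(values(fm)[2, 1:8]), analytic)
})

test_that("intervals outside the epoch window are rejected", {
  ep <- toyEpochs(array(0, dim = c(2, 1, 50)),
                  timeMs = seq(0, 490, by = 10))
  expect_error(extractIntervalMeans(ep, intervalsMs = list(c(600, 800)),
                                    channels = "ch1"),
               "outside the epoch window")
})

test_that("full shrinkage reduces the weights to the class-mean difference", {
  set.seed(11)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- rep(c("target", "nontarget"), each = 100)
  X[y == "target", ] <- X[y == "target", ] + 1
  m <- fitShrinkageLda(X, y, gamma = 1)
  mu <- colMeans(X[y == "target", ]) - colMeans(X[y == "nontarget", ])
  ratio <- ldaWeights(m) / mu
  expect_lt(stats::sd(ratio) / abs(mean(ratio)), 1e-10)
})

test_that("unshrunk LDA matches the textbook closed-form solution in 2-D", {
  set.seed(12)
  n <- 500
  Xp <- cbind(rnorm(n, 1), rnorm(n, 0.5, 2))
  Xn <- cbind(rnorm(n, -1), rnorm(n, -0.5, 2))
  X <- rbind(Xp, Xn)
  y <- rep(c("target", "nontarget"), each = n)
  m <- fitShrinkageLda(X, y, gamma = 0)
  # independent oracle: explicit pooled covariance and 2x2 inversion
  Sp <- stats::cov(Xp); Sn <- stats::cov(Xn)
  S <- ((n - 1) * Sp + (n - 1) * Sn) / (2 * n - 2)
  muD <- colMeans(Xp) - colMeans(Xn)
  wOracle <- solve(S, muD)
  expect_equal(ldaWeights(m), unname(wOracle), tolerance = 1e-6)
  bOracle <- -sum(wOracle * (colMeans(Xp) + colMeans(Xn))) / 2
  expect_equal(ldaBias(m), bOracle, tolerance = 1e-6)
})

test_that("the analytic shrinkage intensity vanishes as n grows", {
  # anisotropic covariance: the scaled-identity target is wrong, so the
  # estimator must abandon it as evidence accumulates
  scales <- seq(0.5, 4, length.out = 8)
  gammas <- vapply(c(50, 500, 5000), function(n) {
    set.seed(n)
    X <- matrix(rnorm(n * 8), n, 8) %*% diag(scales)
    y <- rep(c("target", "nontarget"), length.out = n)
    X[y == "target", 1] <- X[y == "target", 1] + 1
    ldaGamma(fitShrinkageLda(X, y))
  }, numeric(1L))
  expect_true(all(diff(gammas) < 0))
  expect_lt(gammas[3], 0.05)
})

test_that("single-class input and dimension mismatches are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fitShrinkageLda(X, rep("target", 10)), "both classes")
  m <- fitShrinkageLda(X, rep(c("target", "nontarget"), 5))
  expect_error(decisionScores(m, matrix(0, 3, 5)), "dimension mismatch")
})

test_that("decision scores are affine with a zero at the class-mean midpoint", {
  set.seed(13)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- rep(c("target", "nontarget"), 50)
  X[y == "target", ] <- X[y == "target", ] + 0.8
  m <- fitShrinkageLda(X, y)
  mid <- (colMeans(X[y == "target", ]) + colMeans(X[y == "nontarget", ])) / 2
  expect_equal(decisionScores(m, matrix(mid, 1)), 0, tolerance = 1e-10)
  # translating all features shifts every score by the same amount
  shift <- rnorm(4)
  s0 <- decisionScores(m, X)
  s1 <- decisionScores(m, sweep(X, 2, -shift))
  expect_equal(s1 - s0, rep(sum(ldaWeights(m) * shift), 100))
  # explicit affine expansion: score(a*x) = a*w'x + b
  a <- 2.5
  expect_equal(decisionScores(m, a * X), a * (s0 - ldaBias(m)) + ldaBias(m))
})

test_that("AUC matches pairwise enumeration and its boundary values", {
  expect_identical(aucScore(c(1, 2, 3, 10, 11),
                            c(rep("nontarget", 3), rep("target", 2))), 1)
  expect_identical(aucScore(rep(1, 10), rep(c("target", "nontarget"), 5)), 0.5)
  set.seed(14)
  sc <- sample(rnorm(20), 30, replace = TRUE)    # duplicates force ties
  y <- sample(c("target", "nontarget"), 30, replace = TRUE,
              prob = c(0.4, 0.6))
  y[1:2] <- c("target", "nontarget")
  # O(n^2) pairwise oracle with half-count ties
  pos <- which(y == "target"); neg <- which(y == "nontarget")
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  expect_equal(aucScore(sc, y), tot / (length(pos) * length(neg)))
  # invariance under strictly monotone transforms
  expect_equal(aucScore(exp(2 * sc), y), aucScore(sc, y))
})

test_that("chronological folds are contiguous and cover all trials once", {
  ep <- cleanEpochs()
  sub <- amuseBCI:::.subsetEpochs(ep, epochInfo(ep)$condition == "EO")
  cv <- chronologicalCV(sub, k = 5)
  folds <- cv$foldTrials
  all_ <- unlist(folds, use.names = FALSE)
  info <- epochInfo(sub)
  chron <- unique(paste(info$runIndex, info$trialIndex, sep = "."))
  expect_identical(all_, chron)                  # contiguous & exhaustive
  expect_error(chronologicalCV(sub, k = 50), "fewer trials")
})

test_that("a high-SNR synthetic session is decoded almost perfectly", {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 31), 1:2)
  prof <- makeSubjectProfile(1, overrides = c(meanProfileOverrides(),
                                              quietOverrides(0.5)))
  rec <- synthesizeSession(sched, prof, seed = 32)$recording
  ep <- preprocessRecording(rec)
  tab <- classifyByCondition(ep)
  expect_gt(mean(tab$auc), 0.9)
})

test_that("label permutation drives the cross-validated AUC to chance", {
  ep <- cleanEpochs()
  sub <- amuseBCI:::.subsetEpochs(ep, epochInfo(ep)$condition == "EO")
  sub <- selectChannels(sub, c("Fz", "FCz", "Cz", "CPz", "Pz", "POz", "Oz",
                               "C3", "C4", "P3", "P4", "F3", "F4", "PO3",
                               "PO4", "CP1"))
  fm <- extractIntervalMeans(sub, channels = channelLabels(sub))
  y <- epochInfo(sub)$label
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    chronologicalCV(fm, labels = sample(y))$meanAuc
  }, numeric(1L))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("duplicating every feature barely moves the cross-validated AUC", {
  ep <- cleanEpochs()
  sub <- amuseBCI:::.subsetEpochs(ep, epochInfo(ep)$condition == "EO")
  sub <- selectChannels(sub, c("Fz", "FCz", "Cz", "Pz", "POz", "Oz"))
  fm <- extractIntervalMeans(sub, channels = channelLabels(sub))
  base <- chronologicalCV(fm)$meanAuc
  dup <- fm
  dup@values <- cbind(fm@values, fm@values)
  dup@channelLabels <- c(channelLabels(fm), paste0(channelLabels(fm), "b"))
  expect_lt(abs(chronologicalCV(dup)$meanAuc - base), 0.02)
})

test_that("conditions sharing amplitudes decode near-identically", {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 33), 1:10)
  # identical generative parameters in both conditions: any AUC gap is
  # pipeline asymmetry or sampling noise
  prof <- makeSubjectProfile(1, overrides = list(
    n200LatencyMs = 203, n200AmpUV = -1.55, p300LatencyMs = 600,
    p300AmpUV = 1.8, noiseSdUV = 4, alphaAmpUV = 2, blinkRateHz = 0,
    saccadeRateHz = 0))
  rec <- synthesizeSession(sched, prof, seed = 34)$recording
  tab <- classifyByCondition(preprocessRecording(rec))
  byCond <- tapply(tab$auc, tab$condition, mean)
  expect_lt(abs(byCond["EO"] - byCond["EC"]), 0.05)
})
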