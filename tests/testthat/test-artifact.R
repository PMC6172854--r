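frontalToy <- function(data) {
  toyEpochs(data, channelLabels = c("Fp1", "Fp2", "F7", "F8", "F9", "F10",
                                    "Cz", "Pz", "EOGvu")[seq_len(dim(data)[2L])])
}

test_that("peak-to-peak flagging fires exactly on range exceedance", {
  d <- array(0, dim = c(3, 7, 50))
  d[2, 1, ] <- seq(0, 61, length.out = 50)      # 61 µV ramp on Fp1
  d[3, 7, ] <- seq(0, 200, length.out = 50)     # large range on Cz: ignored
  ep <- frontalToy(d)
  flags <- minmaxFlag(ep)
  expect_identical(flags, c(FALSE, TRUE, FALSE))
})

test_that("flags equal a brute-force per-channel range scan on random epochs", {
  set.seed(3)
  d <- array(rnorm(200 * 7 * 30, sd = 25), dim = c(200, 7, 30))
  ep <- frontalToy(d)
  flags <- minmaxFlag(ep)
  oracle <- logical(200)
  for (e in 1:200) {
    r <- FALSE
    for (ch in 1:6)                      # the six frontal channels
      r <- r || (max(d[e, ch, ]) - min(d[e, ch, ]) > 60)
    oracle[e] <- r
  }
  expect_identical(flags, oracle)
})

test_that("missing frontal channels are reported by name", {
  ep <- toyEpochs(array(0, dim = c(2, 2, 10)),
                  channelLabels = c("Cz", "Pz"))
  expect_error(minmaxFlag(ep), "Fp1")
})

test_that("bipolar EOG derivation is exact sample-wise arithmetic", {
  d <- array(0, dim = c(2, 9, 20))
  d[, 5, ] <- 4; d[, 6, ] <- 4                  # F9 == F10
  d[, 2, ] <- 5; d[, 9, ] <- 2                  # Fp2 = 5, EOGvu = 2
  ep <- frontalToy(d)
  eog <- deriveBipolarEOG(ep)
  expect_true(all(eog$eogh == 0))
  expect_true(all(eog$eogv == 3))
  # linearity under scaling
  ep2 <- frontalToy(d * 2.5)
  eog2 <- deriveBipolarEOG(ep2)
  expect_equal(eog2$eogv, eog$eogv * 2.5)
})

test_that("EOG regression removes a channel equal to the regressor and spares orthogonal ones", {
  set.seed(4)
  nEp <- 20; nT <- 50
  h <- matrix(rnorm(nEp * nT), nEp, nT)
  v <- matrix(rnorm(nEp * nT), nEp, nT)
  d <- array(0, dim = c(nEp, 9, nT))
  d[, 5, ] <- h / 2; d[, 6, ] <- -h / 2          # F9 - F10 = h
  d[, 2, ] <- v; d[, 9, ] <- 0                   # Fp2 - EOGvu = v
  d[, 7, ] <- h                                  # Cz equals EOGh exactly
  # Pz: residualized against [1, h, v] so its sample covariance is zero
  raw <- rnorm(nEp * nT)
  X <- cbind(1, as.numeric(t(h)), as.numeric(t(v)))
  d[, 8, ] <- matrix(stats::resid(stats::lm.fit(X, raw)), nEp, nT,
                     byrow = TRUE)
  ep <- frontalToy(d)
  out <- regressOutEOG(ep)
  expect_lt(max(abs(values(out)[, 7, ])), 1e-8)
  expect_equal(values(out)[, 8, ], d[, 8, ], tolerance = 1e-8)
  # residuals are uncorrelated with both regressors
  res <- as.numeric(t(values(out)[, 2, ]))
  expect_lt(abs(stats::cov(res, as.numeric(t(h)))), 1e-8)
  expect_lt(abs(stats::cov(res, as.numeric(t(v)))), 1e-8)
})

test_that("collinear EOG regressors are rejected", {
  d <- array(0, dim = c(5, 9, 30))
  s <- matrix(rnorm(5 * 30), 5, 30)
  d[, 5, ] <- s                                  # EOGh = s (F10 = 0)
  d[, 2, ] <- 2 * s                              # EOGv = 2 s (EOGvu = 0)
  expect_error(regressOutEOG(frontalToy(d)), "rank deficient")
})

test_that("the channel variance rules reject flat and exploded channels", {
  set.seed(5)
  nEp <- 40
  # graded per-channel scales so the healthy variance spread is wide, as in
  # real recordings (the high rule compares against 3 x (P90 - P10))
  sds <- seq(3, 8, length.out = 9)
  d <- array(rnorm(nEp * 9 * 30), dim = c(nEp, 9, 30))
  for (ch in 1:9) d[, ch, ] <- d[, ch, ] * sds[ch]
  d[, 7, ] <- 0                                  # Cz flat
  d[, 8, ] <- d[, 8, ] * 20                      # Pz exploded
  ep <- frontalToy(d)
  rej <- channelVarianceReject(ep)
  expect_true("Cz" %in% rej$label[rej$reason == "low_variance"])
  expect_true("Pz" %in% rej$label[rej$reason == "high_variance"])
  # hand-computed percentile oracle for the high rule
  v <- sapply(1:8, function(ch)                  # scalp channels only
    mean(apply(d[, ch, ], 1, stats::var)))
  q <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
  expect_identical("Pz" %in% rej$label, v[8] > 3 * (q[2] - q[1]))
})

test_that("channels inside a wide healthy variance spread are kept", {
  set.seed(6)
  sds <- seq(3, 8, length.out = 9)               # P90-P10 > max variance / 3
  d <- array(rnorm(40 * 9 * 30), dim = c(40, 9, 30))
  for (ch in 1:9) d[, ch, ] <- d[, ch, ] * sds[ch]
  rej <- channelVarianceReject(frontalToy(d))
  expect_identical(nrow(rej), 0L)
})

test_that("trial variance flags scale outliers and ignore channel order", {
  set.seed(7)
  d <- array(rnorm(30 * 9 * 40), dim = c(30, 9, 40))
  scales <- seq(2, 6, length.out = 30)           # graded per-epoch scales
  for (e in 1:30) d[e, , ] <- d[e, , ] * scales[e]
  d[13, , ] <- d[13, , ] * 20
  ep <- frontalToy(d)
  flags <- trialVarianceFlag(ep)
  expect_true(flags[13])
  expect_false(any(flags[-13]))
  perm <- sample(9)
  epPerm <- toyEpochs(d[, perm, , drop = FALSE],
                      channelLabels = channelLabels(ep)[perm])
  expect_identical(trialVarianceFlag(epPerm), trialVarianceFlag(ep))
})

test_that("P1 equals direct peak-to-peak flagging and leaves data untouched", {
  ep <- cleanEpochs()
  out <- runArtifactPipeline(ep, "P1")
  expect_identical(out$report@flags$minmax60, minmaxFlag(ep))
  expect_identical(values(out$epochs), values(ep))
  # artifact-free synthetic session: almost nothing flagged
  expect_lt(max(out$report@percentFlagged), 1)
})

test_that("EOG regression makes P2 flag fewer epochs than P1 on blink-heavy data", {
  ep <- blinkHeavyEpochs()
  p1 <- runArtifactPipeline(ep, "P1")
  p2 <- runArtifactPipeline(ep, "P2")
  expect_lt(mean(p2$report@percentFlagged), mean(p1$report@percentFlagged))
  # regression shrinks frontal RMS
  rmsF <- function(e) sqrt(mean(values(e)[, 1:2, ]^2))
  expect_lt(rmsF(p2$epochs), rmsF(p1$epochs))
})

test_that("flagged fraction grows with injected blink amplitude", {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 23), 1L)
  pf <- vapply(c(20, 60, 150), function(amp) {
    prof <- makeSubjectProfile(1, overrides = mergeOv(quietOverrides(1),
              list(blinkRateHz = 0.4, blinkAmpUV = amp)))
    rec <- synthesizeSession(sched, prof, seed = 24)$recording
    ep <- preprocessRecording(rec)
    mean(runArtifactPipeline(ep, "P1")$report@percentFlagged)
  }, numeric(1L))
  expect_true(all(diff(pf) >= 0))
  expect_gt(pf[3], pf[1])
})

test_that("strong blinks are caught for nearly all epochs containing them", {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 25), 1L)
  prof <- makeSubjectProfile(1, overrides = mergeOv(quietOverrides(1),
            list(blinkRateHz = 0.3, blinkAmpUV = 150)))   # all >= 105 µV
  out <- synthesizeSession(sched, prof, seed = 26)
  ep <- preprocessRecording(out$recording)
  flags <- minmaxFlag(ep)
  blinks <- out$artifactLog[out$artifactLog$kind == "blink", ]
  onset <- epochInfo(ep)$onsetMs
  # epochs whose window contains a logged blink's central deflection
  peakMs <- blinks$onsetMs + 120
  hit <- vapply(seq_along(onset), function(e)
    any(peakMs > onset[e] - 200 & peakMs < onset[e] + 1200), logical(1L))
  expect_gte(mean(flags[hit]), 0.9)
})
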