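test_that("templates with zero amplitudes are identically zero", {
  p <- makeSubjectProfile(1, overrides = list(n200AmpUV = 0, p300AmpUV = 0))
  tpl <- renderEpochTemplate(p, "target", "EO")
  expect_true(all(tpl == 0))
})

test_that("template extremum at Pz sits at the configured P300 latency and amplitude", {
  p <- makeSubjectProfile(1, overrides = meanProfileOverrides())
  tpl <- renderEpochTemplate(p, "target", "EO")
  tMs <- seq(-200, 1199, by = 1)
  i <- which.max(tpl["Pz", ])
  expect_lte(abs(tMs[i] - 690), 1)
  # unit spatial weight at the map center: peak equals the configured amplitude
  expect_equal(max(tpl["Pz", ]), 1.71, tolerance = 1e-3)
  j <- which.min(tpl["FCz", ])
  expect_lte(abs(tMs[j] - 201), 1)
  # small cross-talk from the P300's spatial tail at FCz is tolerated
  expect_equal(min(tpl["FCz", ]), -1.53, tolerance = 1e-3)
})

test_that("non-target templates are attenuated by the class factors", {
  p <- makeSubjectProfile(1, overrides = meanProfileOverrides())
  tg <- renderEpochTemplate(p, "target", "EC")
  nt <- renderEpochTemplate(p, "nontarget", "EC")
  expect_equal(max(nt["Pz", ]) / max(tg["Pz", ]), 0.15, tolerance = 5e-3)
  expect_equal(min(nt["FCz", ]) / min(tg["FCz", ]), 0.6, tolerance = 5e-3)
})

test_that("a noise- and artifact-free session is the explicit superposition of templates", {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 4), 1L)
  prof <- makeSubjectProfile(1, overrides = c(meanProfileOverrides(),
                                              quietOverrides(0)))
  rec <- synthesizeSession(sched, prof, seed = 2)$recording
  ev <- events(sched)

  # oracle: direct Gaussian-sum evaluation at Pz for a mid-trial window,
  # written independently of the renderer
  montage <- amuseMontage()
  wN <- exp(-((montage$x - montage$x[montage$label == "FCz"])^2 +
              (montage$y - montage$y[montage$label == "FCz"])^2) /
            (2 * 0.45^2))[montage$label == "Pz"]
  target <- ev[ev$isTarget, ][20, ]
  tAbs <- seq(target$onsetMs, target$onsetMs + 1199)   # ms at 1 kHz
  expected <- numeric(length(tAbs))
  for (j in seq_len(nrow(ev))) {
    tRel <- tAbs - ev$onsetMs[j]
    aN <- -1.53 * if (ev$isTarget[j]) 1 else 0.6
    aP <- 1.71 * if (ev$isTarget[j]) 1 else 0.15
    contrib <- wN * aN * exp(-(tRel - 201)^2 / (2 * 40^2)) +
               1 * aP * exp(-(tRel - 690)^2 / (2 * 110^2))
    contrib[tRel < 0 | tRel >= 1200] <- 0    # renderer horizon: 1.2 s
    expected <- expected + contrib
  }
  got <- values(rec)["Pz", target$onsetMs + 1 + 0:1199]
  expect_equal(got, expected, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("recording bookkeeping copies every scheduled event", {
  s <- cleanSession()
  expect_identical(nrow(events(s$recording)), nrow(events(s$schedule)))
  expect_identical(events(s$recording)$onsetMs, events(s$schedule)$onsetMs)
})

test_that("synthesis is bit-identical for identical inputs", {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 4), 1L)
  prof <- makeSubjectProfile(3)
  a <- synthesizeSession(sched, prof, seed = 5)
  b <- synthesizeSession(sched, prof, seed = 5)
  expect_identical(values(a$recording), values(b$recording))
  expect_identical(a$artifactLog, b$artifactLog)
  c_ <- synthesizeSession(sched, prof, seed = 6)
  expect_false(identical(values(a$recording), values(c_$recording)))
})

test_that("zero artifact rates leave the recording unchanged with an empty log", {
  s <- cleanSession()
  prof0 <- makeSubjectProfile(1, overrides = list(blinkRateHz = 0,
                                                  saccadeRateHz = 0))
  out <- injectEyeArtifacts(s$recording, prof0, seed = 1)
  expect_identical(values(out$recording), values(s$recording))
  expect_identical(nrow(out$artifactLog), 0L)
})

test_that("blinks deflect Fp2 and EOGvu with opposite signs", {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 4), 1L)
  prof <- makeSubjectProfile(1, overrides = mergeOv(quietOverrides(0),
                              list(blinkRateHz = 0.3)))
  zero <- synthesizeSession(sched,
            makeSubjectProfile(1, overrides = quietOverrides(0)),
            seed = 2)$recording
  out <- injectEyeArtifacts(zero, prof, seed = 8)
  log <- out$artifactLog
  expect_gt(nrow(log), 0L)
  blink <- log[log$kind == "blink", ][1L, ]
  i <- round(blink$onsetMs) + 120         # near the biphasic peak
  d <- values(out$recording)
  expect_gt(d["Fp2", i], 0)
  expect_lt(d["EOGvu", i], 0)
  expect_equal(unname(sign(d["Fp2", i])), -unname(sign(d["EOGvu", i])))
})

test_that("saccades are antisymmetric on F9/F10 so the bipolar trace doubles", {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 4), 1L)
  prof <- makeSubjectProfile(1, overrides = mergeOv(quietOverrides(0),
                              list(saccadeRateHz = 0.2)))
  zero <- synthesizeSession(sched,
            makeSubjectProfile(1, overrides = quietOverrides(0)),
            seed = 2)$recording
  out <- injectEyeArtifacts(zero, prof, seed = 9)
  log <- out$artifactLog
  sac <- log[log$kind == "saccade", ][1L, ]
  i <- round(sac$onsetMs) + 100            # mid-plateau
  d <- values(out$recording)
  expect_equal(unname(sign(d["F9", i])), -unname(sign(d["F10", i])))
  bipolar <- d["F9", i] - d["F10", i]
  expect_equal(abs(bipolar), 2 * abs(d["F9", i]), tolerance = 0.05)
})

test_that("logged blink counts follow the configured Poisson rate", {
  sched <- subsetRuns(buildSessionSchedule("EC", seed = 4), 1:2)
  prof <- makeSubjectProfile(1, overrides = mergeOv(quietOverrides(0),
            list(blinkRateHz = c(EO = 0, EC = 0.5))))
  out <- synthesizeSession(sched, prof, seed = 3)
  log <- out$artifactLog
  ev <- events(sched)
  ec <- ev[ev$condition == "EC", ]
  tSec <- (max(ec$onsetMs) - min(ec$onsetMs) + 1200 + 2 * 2000) / 1000
  lambda <- 0.5 * tSec
  nBlinks <- sum(log$kind == "blink" & log$condition == "EC")
  expect_lt(abs(nBlinks - lambda), 3 * sqrt(lambda))
  expect_identical(sum(log$condition == "EO"), 0L)
})

test_that("artifact injection requires the periocular montage channels", {
  rec <- toyRecording(matrix(0, 2, 1000), labels = c("Cz", "Pz"))
  expect_error(injectEyeArtifacts(rec, makeSubjectProfile(1), seed = 1),
               "Fp1")
})
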