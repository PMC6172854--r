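test_that("the paired t statistic matches the explicit mean/SE formula", {
  set.seed(31)
  x <- rnorm(15, 1); y <- rnorm(15)
  res <- pairedTTest(x, y)
  d <- x - y
  tOracle <- mean(d) / (stats::sd(d) / sqrt(15))
  expect_equal(res@statistic, tOracle)
  expect_equal(res@pRaw, 2 * stats::pt(-abs(tOracle), df = 14))
  expect_identical(res@n, 15L)
})

test_that("constant paired differences are rejected", {
  expect_error(pairedTTest(c(1, 2, 3), c(0, 1, 2)), "zero variance")
})

test_that("the published P300 latency contrast reproduces t(11) = 2.96", {
  ref <- referencePeakTable()
  res <- pairedTTest(ref$p300LatencyMs.EO, ref$p300LatencyMs.EC)
  expect_equal(round(res@statistic, 2), 2.96)
  expect_equal(round(res@pRaw, 3), 0.013)
})

test_that("the exact signed-rank test reproduces W = 3, p = 0.0024 at n = 12", {
  d <- c(1, 2, -3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  res <- wilcoxonSignedRankExact(d)
  expect_identical(res@statistic, 3)
  expect_equal(res@pRaw, 10 / 4096)
  expect_equal(round(res@pRaw, 4), 0.0024)
})

test_that("uniformly positive differences give the extreme one-sided tail", {
  res <- wilcoxonSignedRankExact(1:12, rep(0, 12), sidedness = "greater")
  expect_equal(res@pRaw, 1 / 4096)
})

test_that("exact signed-rank p equals full enumeration, ties included", {
  set.seed(32)
  for (rep_ in 1:3) {
    d <- round(rnorm(8), 1)
    d[d == 0] <- 0.5
    res <- wilcoxonSignedRankExact(d)
    # independent oracle: enumerate all 256 sign patterns explicitly
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
    sums <- signs %*% r
    w <- min(sum(r[d > 0]), sum(r[d < 0]))
    pOracle <- min(1, 2 * mean(sums <= w + 1e-9))
    expect_equal(res@pRaw, pOracle)
  }
  # tie-free case agrees with the reference implementation's exact p
  x <- c(3.1, -1.2, 0.7, 2.2, -0.4, 1.9, 5.3, -2.8)
  res <- wilcoxonSignedRankExact(x)
  refP <- stats::wilcox.test(x, exact = TRUE)$p.value
  expect_equal(res@pRaw, refP)
})

test_that("zero differences are dropped and all-zero input errors", {
  res <- wilcoxonSignedRankExact(c(0, 0, 1, 2, -3, 4))
  expect_identical(res@n, 4L)
  expect_error(wilcoxonSignedRankExact(rep(0, 5)), "zero")
  expect_error(wilcoxonSignedRankExact(rnorm(30)), "n <= 25")
})

test_that("Holm adjustment matches a hand-stepped step-down oracle", {
  p <- c(0.01, 0.04, 0.03)
  # oracle: sort ascending, multiply by m..1, enforce monotonicity
  ord <- order(p)
  stepped <- p[ord] * (3:1)
  stepped <- cummax(pmin(stepped, 1))
  oracle <- numeric(3); oracle[ord] <- stepped
  expect_equal(holmCorrection(p), oracle)
  expect_equal(holmCorrection(p), c(0.03, 0.06, 0.06))

  expect_identical(holmCorrection(0.2), 0.2)     # m = 1: unchanged
  set.seed(33)
  pr <- runif(6)
  adj <- holmCorrection(pr)
  expect_true(all(adj >= pr))
  expect_true(all(diff(adj[order(pr)]) >= -1e-12))
  expect_error(holmCorrection(c(0.1, 1.2)), "0, 1")
})

test_that("the exact binomial tail matches direct summation", {
  expect_equal(binomialPreferenceTest(12, 12)@pRaw, 1 / 4096)
  expect_equal(binomialPreferenceTest(9, 12)@pRaw, 299 / 4096)
  # direct summation oracle
  expect_equal(binomialPreferenceTest(9, 12)@pRaw,
               sum(choose(12, 9:12)) / 2^12)
  ps <- vapply(0:12, function(k) binomialPreferenceTest(k, 12)@pRaw,
               numeric(1L))
  expect_true(all(diff(ps) <= 0))                # non-increasing in k
  expect_error(binomialPreferenceTest(13, 12), "kSuccesses")
})

test_that("rating summaries compute descriptives and detect shifted conditions", {
  set.seed(34)
  subj <- sprintf("S%02d", 1:12)
  items <- c("fatigue", "eye_movements", "valence", "arousal")
  mk <- function(shift, sd_) do.call(rbind, lapply(items, function(it) {
    eo <- pmin(5, pmax(1, round(rnorm(12, 3, sd_))))
    ec <- pmin(5, pmax(1, eo + shift + round(rnorm(12, 0, 0.5))))
    rbind(data.frame(subject = subj, item = it, condition = "EO",
                     rating = eo),
          data.frame(subject = subj, item = it, condition = "EC",
                     rating = ec))
  }))
  shifted <- mk(1, 0.8)
  res <- summarizeRatings(shifted,
                          preferences = c(rep("EC", 9), "EO", "undecided",
                                          "undecided"))
  expect_true(all(res$tests$pRaw[res$tests$statistic == "t"] < 0.05))
  expect_identical(nrow(res$tests), 5L)
  expect_true(all(res$tests$pAdjusted >= res$tests$pRaw))
  # descriptive means equal hand-computed column means
  one <- shifted[shifted$item == "fatigue" & shifted$condition == "EO", ]
  expect_equal(res$descriptives$mean[res$descriptives$item == "fatigue" &
                                     res$descriptives$condition == "EO"],
               mean(one$rating))

  # identical ratings across conditions: null results
  null_ <- mk(0, 0.8)
  null_$rating[null_$condition == "EC"] <-
    null_$rating[null_$condition == "EO"]
  resNull <- summarizeRatings(null_)
  expect_true(all(resNull$tests$value == 0))
  expect_true(all(resNull$tests$pRaw == 1))
})

test_that("subjects missing a condition are excluded with a warning", {
  tab <- data.frame(subject = c("S1", "S1", "S2"),
                    item = "fatigue",
                    condition = c("EO", "EC", "EO"),
                    rating = c(3, 4, 2))
  tab2 <- rbind(tab, data.frame(subject = c("S3", "S3"), item = "fatigue",
                                condition = c("EO", "EC"), rating = c(1, 5)))
  expect_warning(res <- summarizeRatings(tab2), "excluded")
  expect_identical(res$tests$n[1L], 2L)
})
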