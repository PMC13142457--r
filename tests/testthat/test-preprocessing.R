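test_that("z-scoring yields unit whole-session moments per feature", {
  ses <- sesStd()$session   # already z-scored by the fixture
  flat <- matrix(featureTensor(ses), ncol = nFeatures(ses))
  expect_lt(max(abs(colMeans(flat))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(sweep(flat, 2, colMeans(flat))^2)) - 1)), 1e-10)
})

test_that("z-scoring matches hand-computed values and zeroes constants", {
  ## 3-trial, 1-bin, 2-feature toy with a hand-computed oracle
  set <- buildFullFactorial(c("K", "N"), 1)
  x <- array(0, dim = c(3, 1, 2))
  x[, 1, 1] <- c(1, 2, 3)
  x[, 1, 2] <- 7                           # constant feature
  ses <- new("SessionData", features = x, labels = c(1L, 2L, 1L),
             conditionSet = set,
             events = data.frame(cue_onset = 0, cue_offset = 0.1,
                                 go_cue = 0.2, speech_onset = 0.3)[c(1, 1, 1), ],
             blockIds = c(1L, 1L, 1L), binWidth = 0.02,
             featureNames = c("a", "b"))
  z <- zscoreSession(ses)
  ## population sd of (1,2,3) is sqrt(2/3)
  expect_equal(as.numeric(z@features[, 1, 1]),
               (c(1, 2, 3) - 2) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(as.numeric(z@features[, 1, 2]), c(0, 0, 0))
})

test_that("gaussian smoothing preserves constants and mass", {
  const <- matrix(5, 50, 1)
  sm <- phonoplan:::gaussSmoothMatrix(const, 3)
  expect_lt(max(abs(sm - 5)), 1e-10)
  ## unit impulse spreads into a discretized gaussian with sd = sigma bins
  imp <- matrix(0, 101, 1); imp[51] <- 1
  sm <- phonoplan:::gaussSmoothMatrix(imp, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-10)
  idx <- seq_len(101) - 51
  expect_equal(sum(sm * idx), 0, tolerance = 1e-10)
  expect_equal(sqrt(sum(sm * idx^2)), 3, tolerance = 0.05)
})

test_that("smoothing commutes with trial averaging", {
  set.seed(1)
  x <- array(rnorm(10 * 40 * 2), dim = c(10, 40, 2))
  smoothed <- apply(x, 1, function(tr)
    phonoplan:::gaussSmoothMatrix(matrix(tr, 40, 2), 3), simplify = FALSE)
  avgThenSmooth <- phonoplan:::gaussSmoothMatrix(apply(x, c(2, 3), mean), 3)
  smoothThenAvg <- Reduce(`+`, smoothed) / 10
  expect_lt(max(abs(avgThenSmooth - smoothThenAvg)), 1e-10)
})

test_that("smoothPSTH returns trial-averaged traces with CIs", {
  fx <- sesStd()
  trials <- which(trialLabels(fx$session) == 1L)
  ps <- smoothPSTH(fx$session, trials, epochWindow("cue_onset", 0, 0.6),
                   nBoot = 500L)
  expect_equal(dim(ps$mean), c(30L, 64L))
  expect_true(all(ps$lower <= ps$mean + 1e-12))
  expect_true(all(ps$upper >= ps$mean - 1e-12))
  expect_error(smoothPSTH(fx$session, integer(0), prepWin()), "empty group")
})

test_that("bootstrap CI half-width shrinks like one over sqrt(n)", {
  set <- buildFullFactorial(c("K", "N"), 1)
  cfg <- generatorConfig(nFeatures = 8L, snr = 0)
  code <- makeGroundTruthCode(set, cfg, seed = 31)
  width <- vapply(c(20L, 80L), function(reps) {
    plan <- makeTrialPlan(set, reps, seed = 32)
    ses <- simulateSession(code, plan, set, cfg, seed = 33)
    set.seed(34)
    ps <- smoothPSTH(ses, which(trialLabels(ses) == 1L),
                     epochWindow("cue_onset", 0, 0.3), nBoot = 800L)
    mean(ps$upper - ps$lower)
  }, numeric(1))
  expect_equal(width[1] / width[2], 2, tolerance = 0.35)
})

test_that("sliding windows tile a span as floor((span-width)/step)+1", {
  fx <- sesStd()
  ext <- extractWindows(fx$session, epochWindow("cue_onset", 0, 1.0),
                        mode = "sliding", widthMs = 100, stepMs = 60)
  expect_equal(length(ext$starts), 16L)
  ## width = full span reduces to average mode
  one <- extractWindows(fx$session, epochWindow("cue_onset", 0, 0.5),
                        mode = "sliding", widthMs = 500, stepMs = 60)
  avg <- extractWindows(fx$session, epochWindow("cue_onset", 0, 0.5),
                        mode = "average")
  expect_equal(length(one$starts), 1L)
  expect_equal(one$windows[[1]]$matrix, avg$matrix)
})

test_that("windows are half-open: a bin starting at end is excluded", {
  fx <- sesNoiseless()
  a <- extractWindows(fx$session, epochWindow("cue_onset", 0, 0.10),
                      mode = "bins")
  expect_equal(length(a$time), 5L)           # bins at 0,20,40,60,80 ms
  expect_equal(a$time, c(0, 0.02, 0.04, 0.06, 0.08))
  b <- extractWindows(fx$session, epochWindow("cue_onset", 0.10, 0.20),
                      mode = "bins")
  expect_equal(b$time[1], 0.10)              # bin starting at 0.10 included
})

test_that("trials not covering the window are dropped and counted", {
  fx <- sesStd()
  ## a window before recording start covers no trial
  expect_error(extractWindows(fx$session, epochWindow("cue_onset", -2, -1.5),
                              mode = "average"), "empty selection")
  ## averaged noiseless windows equal the ground-truth epoch mean
  nl <- sesNoiseless()
  ext <- extractWindows(nl$session, prepWin(0.8), mode = "average")
  expect_equal(ext$nDropped, 0L)
})
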