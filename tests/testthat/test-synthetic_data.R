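test_that("ground-truth code realizes requested cross-position cosines", {
  set <- set27()
  cfg <- generatorConfig(nFeatures = 64L)
  for (c0 in c(0, 0.6, 1)) {
    code <- makeGroundTruthCode(set, cfg, alignment = c0, seed = 7)
    expect_lt(abs(codeAlignment(code, 2, 3) - c0), 1e-6)
    expect_lt(abs(codeAlignment(code, 1, 2) - c0), 1e-6)
  }
  ## infeasible Gram target
  A <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(makeGroundTruthCode(set, cfg, alignment = A),
               "construction error")
})

test_that("phoneme vectors are zero-sum, unit, equidistant; axes orthogonal", {
  code <- sesStd()$code
  b <- code@phonemeVectors
  for (p in 1:3) {
    B <- matrix(b[p, , ], nrow = 3)
    expect_lt(max(abs(colSums(B))), 1e-8)               # zero-sum gauge
    nrm <- sqrt(rowSums(B^2))
    expect_lt(max(abs(nrm - 1)), 1e-8)                  # unit norm
    d12 <- sqrt(sum((B[1, ] - B[2, ])^2))
    d13 <- sqrt(sum((B[1, ] - B[3, ])^2))
    expect_lt(abs(d12 - d13), 1e-8)                     # equidistant
    for (j in 1:3) {
      expect_lt(abs(sum(B[j, ] * code@lengthAxis)), 1e-6)
      expect_lt(abs(sum(B[j, ] * code@boundaryAxis)), 1e-6)
    }
  }
})

test_that("trial plans are balanced, jitter-aware and seed-reproducible", {
  set <- set27()
  plan <- makeTrialPlan(set, 10L, seed = 5)
  expect_equal(nrow(plan), 270L)
  expect_true(all(table(plan$condition) == 10L))
  ## zero jitter: identical event times across trials
  expect_equal(length(unique(plan$go_cue)), 1L)
  ## determinism
  plan2 <- makeTrialPlan(set, 10L, seed = 5)
  expect_identical(plan, plan2)
  ## jitter respects the declared range and stays per-trial
  pj <- makeTrialPlan(set, 2L, epochSpec(delayJitter = 0.4), seed = 6)
  expect_true(all(pj$go_cue >= 2.0 - 1e-12 & pj$go_cue <= 2.4 + 1e-12))
  expect_gt(length(unique(pj$go_cue)), 1L)
  ## rest trials appended as NA labels
  pr <- makeTrialPlan(set, 1L, nRest = 5L, seed = 7)
  expect_equal(sum(is.na(pr$condition)), 5L)
})

test_that("noiseless sessions are an exact linear function of the labels", {
  fx <- sesNoiseless()
  ses <- fx$session
  gt <- groundTruthMeans(fx$code, fx$set)
  ext <- extractWindows(ses, prepWin(0.8), mode = "average")
  labs <- trialLabels(ses)[ext$trials]
  nL <- fx$code@nLatent
  for (i in seq_along(labs)) {
    expect_lt(max(abs(ext$matrix[i, 1:nL] - gt$prep[labs[i], ])), 1e-10)
    expect_lt(max(abs(ext$matrix[i, nL + (1:nL)] - gt$prep[labs[i], ])), 1e-10)
  }
})

test_that("same seed reproduces a bit-identical session", {
  fx <- sesStd()
  again <- simulateSession(fx$code, fx$plan, fx$set, fx$cfg, seed = 103)
  expect_identical(zscoreSession(again)@features, fx$session@features)
})

test_that("empirical condition means converge to the ground truth", {
  ## Monte-Carlo: with many repeats the prep-window empirical mean of each
  ## feature lies within 3 standard errors of the noiseless mean for >= 99%
  ## of (condition, feature) cells
  set <- buildFullFactorial(c("K", "N"), 1)
  cfg <- generatorConfig(nFeatures = 250L, snr = 2)
  code <- makeGroundTruthCode(set, cfg, alignment = 0.5, seed = 8)
  spec <- epochSpec(cue = 0.3, delay = 0.5, react = 0.3, post = 0.2)
  plan <- makeTrialPlan(set, 400L, spec, seed = 9)
  ses <- simulateSession(code, plan, set, cfg, seed = 10)
  ext <- extractWindows(ses, prepWin(0.4), mode = "average")
  labs <- trialLabels(ses)[ext$trials]
  gt <- groundTruthMeans(code, set)$prep
  ## amplitude used by the simulator at this snr
  ampl <- cfg$snr / sqrt(sum(apply(gt, 2, var)))
  nBinW <- round(0.4 / ses@binWidth)
  se <- 1 / sqrt(nBinW * 400)           # unit noise averaged bins x trials
  hits <- 0L; total <- 0L
  for (ci in 1:2) {
    emp <- colMeans(ext$matrix[labs == ci, , drop = FALSE])
    truth <- rep(ampl * gt[ci, ], 2)   # both streams read the same latent
    hits <- hits + sum(abs(emp - truth) <= 3 * se)
    total <- total + length(emp)
  }
  expect_gte(hits / total, 0.99)
})

test_that("poisson mode produces counts with variance close to the mean", {
  set <- buildFullFactorial(c("K", "N"), 1)
  cfg <- generatorConfig(nFeatures = 16L, snr = 1, noiseModel = "poisson")
  code <- makeGroundTruthCode(set, cfg, seed = 11)
  plan <- makeTrialPlan(set, 60L, seed = 12)
  ses <- simulateSession(code, plan, set, cfg, seed = 13)
  x <- featureTensor(ses)
  expect_true(all(x == round(x)))
  expect_true(all(x >= 0))
  ## per feature, pooled over prep bins of one condition
  ext <- extractWindows(ses, prepWin(0.8), mode = "bins")
  labs <- trialLabels(ses)[ext$trials]
  sel <- ext$tensor[labs == 1, , , drop = FALSE]
  m <- apply(sel, 3, mean)
  v <- apply(sel, 3, function(x) var(as.numeric(x)))
  expect_lt(median(abs(v / m - 1)), 0.25)
})

test_that("with boundaryGain 1 contexts differ only along the boundary axis", {
  ws <- buildWordBoundarySet(inv3, 4, 2)
  cfg <- generatorConfig(nFeatures = 64L, snr = Inf)
  code <- makeGroundTruthCode(ws, cfg, alignment = 0.5, boundaryGain = 1,
                              seed = 14)
  gt <- groundTruthMeans(code, ws)$prep
  isTwo <- vapply(ws@segmentation, length, integer(1)) > 0L
  key <- apply(ws@consonants, 1L, paste, collapse = ".")
  for (k in unique(key)[1:10]) {
    d <- gt[key == k & isTwo, ] - gt[key == k & !isTwo, ]
    resid <- d - sum(d * code@boundaryAxis) * code@boundaryAxis
    expect_lt(max(abs(resid)), 1e-10)
  }
})

test_that("per-block drift shifts block means by a constant offset", {
  set <- buildFullFactorial(c("K", "N"), 1)
  cfg <- generatorConfig(nFeatures = 16L, snr = 0, driftSd = 5)
  code <- makeGroundTruthCode(set, cfg, seed = 15)
  plan <- makeTrialPlan(set, 40L, nBlocks = 2L, seed = 16)
  ses <- simulateSession(code, plan, set, cfg, seed = 17)
  flat <- apply(featureTensor(ses), c(1, 3), mean)
  mdiff <- colMeans(flat[blockIds(ses) == 1, ]) - colMeans(flat[blockIds(ses) == 2, ])
  ## drift sd dominates the sampling noise of the block means
  expect_gt(sd(mdiff), 1)
  ## block-subtracted z-scoring removes it
  z <- zscoreSession(ses, blockSubtract = TRUE)
  flatZ <- apply(featureTensor(z), c(1, 3), mean)
  mdiffZ <- colMeans(flatZ[blockIds(z) == 1, ]) - colMeans(flatZ[blockIds(z) == 2, ])
  expect_lt(max(abs(mdiffZ)), 0.05)
})

test_that("non-compositional codes have no additive structure", {
  set <- set27()
  cfg <- generatorConfig(nFeatures = 64L)
  rc <- makeNonCompositionalCode(set, cfg, seed = 18)
  D <- buildDesignMatrix(set, seq_len(27))$X
  proj <- qr.Q(qr(D))
  S <- rc@epochSignals$prep
  expect_lt(max(abs(t(proj) %*% S)), 1e-10)
  expect_gt(sum(S^2), 0)
})
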