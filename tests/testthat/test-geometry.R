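test_that("marginal means reduce to condition means and the grand mean", {
  fx <- sesNoiseless()
  ext <- extractWindows(fx$session, prepWin(0.8), mode = "average")
  labs <- trialLabels(fx$session)[ext$trials]
  X <- ext$matrix
  ## all slots kept: per-condition means
  mm <- marginalMeans(X, fx$set, labs, keepSlots = 1:3)
  expect_equal(nrow(mm$means), 27L)
  i <- which(labs == 5L)
  key <- paste(fx$set@consonants[5, ], collapse = ".")
  expect_equal(unname(mm$means[key, ]), unname(colMeans(X[i, , drop = FALSE])))
  ## no slots kept: grand mean
  gm <- marginalMeans(X, fx$set, labs, keepSlots = integer(0))
  expect_equal(unname(gm$means[1, ]), unname(colMeans(X)))
  expect_error(marginalMeans(X, fx$set, labs, keepSlots = 9L), "pattern")
})

test_that("noiseless marginal means equal the generative algebra", {
  ## balanced factorial: mean of *ah*ahSH = baseline + g3 * b3[SH]
  ## (slot-1/2 contributions cancel by the zero-sum gauge)
  fx <- sesNoiseless()
  ext <- extractWindows(fx$session, prepWin(0.8), mode = "average")
  labs <- trialLabels(fx$session)[ext$trials]
  mm <- marginalMeans(ext$matrix, fx$set, labs, keepSlots = 3L)
  code <- fx$code
  nL <- code@nLatent
  lenTerm <- code@lengthGain * 3 * code@lengthAxis   # constant across the set
  for (q in inventory(fx$set)) {
    j <- match(q, inventory(fx$set))
    truth <- code@baseline + lenTerm + code@gains[3] * code@phonemeVectors[3, j, ]
    expect_lt(max(abs(mm$means[q, 1:nL] - truth)), 1e-10)
  }
})

test_that("displacements nest, cancel within base groups, and mirror the code", {
  fx <- sesNoiseless()
  ext <- extractWindows(fx$session, prepWin(0.8), mode = "average")
  labs <- trialLabels(fx$session)[ext$trials]
  base <- marginalMeans(ext$matrix, fx$set, labs, keepSlots = 3L)
  ref <- marginalMeans(ext$matrix, fx$set, labs, keepSlots = c(2L, 3L))
  disp <- displacementVectors(base, ref)
  expect_equal(nrow(disp$vectors), 9L)
  ## count-weighted zero-sum within each base group
  for (bk in unique(disp$baseKey)) {
    rows <- disp$baseKey == bk
    ws <- colSums(disp$vectors[rows, , drop = FALSE] * disp$counts[rows])
    expect_lt(max(abs(ws)), 1e-9)
  }
  ## refined = base: all-zero vectors
  z <- displacementVectors(base, base)
  expect_lt(max(abs(z$vectors)), 1e-12)
  ## non-nested groupings rejected
  expect_error(displacementVectors(ref, base), "grouping error")
  ## noiseless: like-phoneme slot-2 displacements identical across slot-3
  ## contexts (generative law)
  for (q in inventory(fx$set)) {
    rows <- which(disp$refinedKeys$C2 == q)
    d <- disp$vectors[rows, , drop = FALSE]
    expect_lt(max(abs(sweep(d, 2, colMeans(d)))), 1e-9)
  }
})

test_that("displacement cosines recover the generator alignment", {
  fx <- sesStd()
  ext <- extractWindows(fx$session, prepWin(), mode = "average")
  labs <- trialLabels(fx$session)[ext$trials]
  base <- marginalMeans(ext$matrix, fx$set, labs, keepSlots = 3L)
  ref <- marginalMeans(ext$matrix, fx$set, labs, keepSlots = c(2L, 3L))
  disp <- displacementVectors(base, ref)
  ## slot-2 displacement direction per phoneme (averaged over contexts) vs
  ## slot-3 class-mean displacement direction for the same phoneme
  grand <- marginalMeans(ext$matrix, fx$set, labs, integer(0))
  d3 <- displacementVectors(grand, base)
  cosv <- vapply(inventory(fx$set), function(q) {
    v2 <- colMeans(disp$vectors[disp$refinedKeys$C2 == q, , drop = FALSE])
    v3 <- d3$vectors[rownames(base$means) == q, ]
    sum(v2 * v3) / sqrt(sum(v2^2) * sum(v3^2))
  }, numeric(1))
  expect_lt(abs(mean(cosv) - 0.6), 0.12)
})

test_that("plane variance is exact for coplanar and symmetric point sets", {
  set.seed(51)
  ## coplanar points in 5-d
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  pts <- matrix(rnorm(18), 9, 2) %*% t(basis)
  expect_equal(planeVariance2D(pts), 1, tolerance = 1e-12)
  ## three equal-variance orthogonal directions -> 2/3
  ax <- rbind(diag(3), -diag(3))
  expect_equal(planeVariance2D(ax), 2 / 3, tolerance = 1e-12)
  ## matches a brute-force eigendecomposition of the covariance
  pts <- matrix(rnorm(45), 9, 5)
  ev <- eigen(cov(pts))$values
  expect_equal(planeVariance2D(pts), sum(ev[1:2]) / sum(ev), tolerance = 1e-10)
  ## rigid rotation leaves the fraction unchanged
  R <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(planeVariance2D(pts %*% R), planeVariance2D(pts), tolerance = 1e-10)
  expect_error(planeVariance2D(pts[1:2, ]), "degenerate")
})

test_that("compositional prediction is exact under self-donation", {
  set.seed(52)
  pts <- matrix(rnorm(90 * 3), 90, 3)
  lens <- rep(c("1", "2", "3"), each = 30)
  phs <- rep(rep(c("K", "N", "SH"), each = 10), 3)
  ## when a class's own length is the sole donor, no scaling applies and the
  ## prediction reproduces the class mean exactly
  for (L in c("1", "2", "3")) {
    cpL <- compositionalPredict(pts, lens, phs, donors = L)
    own <- cpL$keys$length == L
    expect_equal(cpL$predicted[own, ], cpL$observed[own, ], tolerance = 1e-10)
  }
})

test_that("compositional prediction separates true from scrambled codes", {
  cfg <- generatorConfig(nFeatures = 64L, snr = 2)
  mset <- setMixed()
  code <- makeGroundTruthCode(mset, cfg, alignment = 0.6, seed = 53)
  plan <- makeTrialPlan(mset, 12L, seed = 54)
  ses <- zscoreSession(simulateSession(code, plan, mset, cfg, seed = 55))
  ext <- extractWindows(ses, epochWindow("go_cue", -0.6, 0), mode = "average")
  labs <- trialLabels(ses)[ext$trials]
  lens <- as.character(mset@lengthClass[labs])
  phs <- phonoplan:::slotConsonant(mset, labs, 1L)
  cp <- compositionalPredict(ext$matrix, lens, phs)
  expect_gt(cp$conditionAveragedR2, 0.85)
  ## permutation null collapses it
  set.seed(56)
  cpn <- compositionalPredict(ext$matrix, lens, phs, nPerm = 30L)
  expect_lt(cpn$permutation$p, 0.1)
})

test_that("marginal correlations isolate phoneme structure from length offsets", {
  cfg <- generatorConfig(nFeatures = 64L, snr = 4)
  mset <- setMixed()
  ## orthogonal positions: cross-position like-phoneme correlation ~ 0 after
  ## removing the shared length offset
  code <- makeGroundTruthCode(mset, cfg, alignment = 0, lengthGain = 3,
                              seed = 57)
  plan <- makeTrialPlan(mset, 12L, seed = 58)
  ses <- zscoreSession(simulateSession(code, plan, mset, cfg, seed = 59))
  ext <- extractWindows(ses, epochWindow("go_cue", -0.6, 0), mode = "average")
  labs <- trialLabels(ses)[ext$trials]
  mc <- marginalCorrelationMatrix(ext$matrix, mset, labs,
                                  subtractLengthMeans = TRUE)
  expect_true(all(abs(diag(mc$correlation) - 1) < 1e-9, na.rm = TRUE))
  g <- mc$groups
  cross <- c()
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    if (g$length[i] == 3 && g$length[j] == 3 && g$position[i] < g$position[j] &&
        g$phoneme[i] == g$phoneme[j])
      cross <- c(cross, mc$correlation[i, j])
  }
  expect_lt(mean(abs(cross)), 0.35)
  ## without subtraction and a strong length axis, within-length blocks share
  ## a positive offset
  mc0 <- marginalCorrelationMatrix(ext$matrix, mset, labs,
                                   subtractLengthMeans = FALSE)
  sameLen <- outer(g$length, g$length, "==") & !diag(nrow(g))
  expect_gt(mean(mc0$correlation[sameLen], na.rm = TRUE),
            mean(mc$correlation[sameLen], na.rm = TRUE))
})
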