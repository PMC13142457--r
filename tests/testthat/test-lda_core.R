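test_that("diag-LDA subspace matches a dense eigensolve on random instances", {
  expect_lt(ldaOracleWorstAngle(100L, seed = 42L), 1e-8)
})

test_that("two 1-D classes give a single component along the axis", {
  set.seed(2)
  X <- cbind(c(rnorm(40, -1), rnorm(40, 1)))
  fit <- fitDiagLDA(X, rep(c("a", "b"), each = 40))
  expect_equal(ncol(fit@projection), 1L)
  expect_gt(fit@projection[1, 1], 0)    # sign convention
})

test_that("K classes retain exactly K-1 components", {
  set.seed(3)
  X <- matrix(rnorm(60 * 8), 60, 8) + matrix(rnorm(3 * 8), 3, 8)[rep(1:3, 20), ] * 2
  fit <- fitDiagLDA(X, rep(1:3, 20))
  expect_equal(ncol(fit@projection), 2L)
  expect_true(all(diff(fit@eigenvalues) <= 1e-12))   # descending order
  expect_error(fitDiagLDA(X, rep(1, 60)), "label error")
})

test_that("projection is X V and class means separate when lambda1 > 0", {
  set.seed(4)
  X <- matrix(rnorm(30 * 5), 30, 5) + matrix(rnorm(3 * 5), 3, 5)[rep(1:3, 10), ]
  fit <- fitDiagLDA(X, rep(1:3, 10))
  expect_equal(ldaProject(fit, X), X %*% fit@projection)
  pm <- ldaProject(fit, fit@classMeans)
  expect_gt(min(dist(pm)), 0)
  expect_error(ldaProject(fit, matrix(0, 2, 4)), "shape error")
})

test_that("feature rescaling leaves the discriminant subspace unchanged", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6) + matrix(rnorm(2 * 6), 2, 6)[rep(1:2, 20), ]
  f1 <- fitDiagLDA(X, rep(1:2, 20))
  f2 <- fitDiagLDA(X * 7.3, rep(1:2, 20))
  expect_lt(max(principalAngles(f1@projection, f2@projection)), 1e-8)
})

test_that("binary discriminant scores behave at the midpoint and the means", {
  ## 2-feature toy with hand-computed oracle
  X <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2),
             c(6, 0), c(6, 2), c(8, 0), c(8, 2))
  lab <- rep(c("A", "B"), each = 4)
  fit <- fitDiagLDA(X, lab)
  mid <- (colMeans(X[1:4, ]) + colMeans(X[5:8, ])) / 2
  sc <- binaryDiscriminant(fit, mid)
  expect_equal(sc$score, 0, tolerance = 1e-10)
  expect_equal(sc$prob, 0.5, tolerance = 1e-10)
  scA <- binaryDiscriminant(fit, colMeans(X[1:4, ]))
  expect_gt(scA$score, 0)
  expect_identical(scA$predicted, "A")
  ## hand-computed: projection v = (mA - mB) / d elementwise, score as inner
  ## product of (proj(x) - proj(mid)) with (proj(mA) - proj(mB))
  v <- fit@projection
  x <- c(1, 1)
  manual <- sum(((x - mid) %*% v) * ((colMeans(X[1:4, ]) - colMeans(X[5:8, ])) %*% v))
  expect_equal(binaryDiscriminant(fit, x)$score, manual, tolerance = 1e-10)
  expect_error(binaryDiscriminant(fitDiagLDA(X, rep(c("A", "B", "C"), c(3, 3, 2))), x),
               "binary-only")
})

test_that("rank AUC handles perfect, chance and tied scores", {
  expect_equal(aucScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(aucScore(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_equal(aucScore(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0)), 0.5)
  set.seed(6)
  scores <- rnorm(10000); labels <- sample(rep(0:1, 5000))
  expect_equal(aucScore(scores, labels), 0.5, tolerance = 0.02)
  ## invariance under strictly monotone transforms
  s <- rnorm(200); l <- rbinom(200, 1, 0.5)
  expect_equal(aucScore(s, l), aucScore(plogis(3 * s + 1), l))
  expect_equal(aucScore(s, l), aucScore(exp(s), l))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (r in 1:5) {
    s <- rnorm(60) + rep(c(0, 0.8), each = 30)
    l <- rep(c(0, 1), each = 30)
    expect_equal(aucScore(s, l),
                 as.numeric(suppressMessages(pROC::auc(l, s, direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("empirical AUC of unit-variance classes matches the closed form", {
  set.seed(8)
  delta <- 1
  s <- c(rnorm(2000), rnorm(2000, delta))
  l <- rep(0:1, each = 2000)
  expect_equal(aucScore(s, l), pnorm(delta / sqrt(2)), tolerance = 0.02)
})

test_that("balanced accuracy normalizes between chance and perfect", {
  truth <- rep(c("a", "b", "c", "d"), each = 10)
  perfect <- evaluateDecoding(truth, truth)
  expect_equal(perfect$balancedAccuracy, 1)
  expect_equal(perfect$normalizedBA, 1)
  uniform <- evaluateDecoding(rep("a", 40), truth)
  expect_equal(uniform$balancedAccuracy, 0.25)
  expect_equal(uniform$normalizedBA, 0)
  expect_equal(perfect$chance, 0.25)
  cm <- evaluateDecoding(truth, truth, confusion = TRUE)$confusion
  expect_true(all(abs(rowSums(cm) - 1) < 1e-12))
  expect_error(evaluateDecoding(rep("a", 5), rep("a", 5)), "degenerate")
})

test_that("cross-validation scores each sample exactly once, reproducibly", {
  set.seed(9)
  X <- matrix(rnorm(30 * 4), 30, 4)
  lab <- rep(c("a", "b"), 15)
  cv <- crossValidate(X, lab, strategy = "loo")
  expect_equal(cv$nFits, 30L)
  expect_false(anyNA(cv$scores$prob))
  f1 <- cvFolds(lab, "stratified", k = 5, seed = 10)
  f2 <- cvFolds(lab, "stratified", k = 5, seed = 10)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  ## folds preserve class proportions
  expect_true(all(table(f1, lab) == 3))
  expect_error(cvFolds(lab, "stratified", k = 16), "fold error")
})
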