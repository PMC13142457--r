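## Diagonal-regularized linear discriminant analysis.
##
## The between-class scatter B = sum_k n_k (mu_k - mu)'(mu_k - mu) measures
## how far each class mean strays from the global mean; the within-class
## scatter W accumulates squared deviations of samples around their own
## class mean. Estimating and inverting the full W is unstable at typical
## trial counts, so only its diagonal D is retained (features conditionally
## independent given class). The discriminant directions are the
## eigenvectors of D^-1 B, of which at most K - 1 carry signal.

#' Fit a diagonal-regularized LDA model
#'
#' @param X samples x features numeric matrix.
#' @param labels class label per sample (any atomic type; coerced to
#'   character; class order = order of first appearance sorted by
#'   `unique()` on the factor levels supplied, otherwise sorted).
#' @param varFloor additive floor applied to the within-class scatter
#'   diagonal; defaults to `1e-8 + 1e-6 * mean(d)` to guard zero-variance
#'   features.
#' @return an [LDAModel-class]. Components are sorted by descending
#'   eigenvalue, and each column's sign is fixed so its largest-magnitude
#'   entry is positive, making projections reproducible.
#' @export
fitDiagLDA <- function(X, labels, varFloor = NULL) {
  X <- as.matrix(X)
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  classes <- levels(f)
  K <- length(classes)
  if (K < 2L) stop("label error: need >= 2 classes")
  nk <- as.integer(table(f))
  if (any(nk < 1L)) stop("label error: class with 0 samples")
  N <- nrow(X)
  mu <- colMeans(X)
  Mk <- do.call(rbind, lapply(classes, function(cl)   # K x features class means
    colMeans(X[f == cl, , drop = FALSE])))
  ## within-class scatter diagonal
  d <- colSums(X^2) - colSums(Mk^2 * nk)
  if (is.null(varFloor)) varFloor <- 1e-8 + 1e-6 * mean(d)
  d <- pmax(d, 0) + varFloor
  ## eigenproblem via the symmetric form D^-1/2 B D^-1/2:
  ## B = C' C with C = sqrt(n_k) (mu_k - mu), K x features
  C <- sweep(Mk, 2L, mu) * sqrt(nk)
  Cs <- sweep(C, 2L, sqrt(d), "/")                 # K x features
  ## eigen in the K-dim row space: Cs' Cs shares nonzero spectrum with Cs Cs'
  G <- Cs %*% t(Cs)                                # K x K
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ncomp <- min(K - 1L, sum(eg$values > max(eg$values[1], 0) * 1e-12))
  ncomp <- max(ncomp, 1L)
  lam <- pmax(eg$values[seq_len(ncomp)], 0)
  ## u = Cs' w / sqrt(lambda) are unit eigenvectors of Cs'Cs; V = D^-1/2 u
  U <- t(Cs) %*% eg$vectors[, seq_len(ncomp), drop = FALSE]
  U <- sweep(U, 2L, sqrt(pmax(lam, 1e-300)), "/")
  V <- sweep(U, 1L, sqrt(d), "/")
  ## sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  new("LDAModel",
      classes = classes, globalMean = mu, classMeans = Mk,
      classCounts = nk, totalCount = as.integer(N),
      diagWithin = d, projection = V, eigenvalues = lam)
}

#' Project data into the discriminant subspace
#'
#' @param model an [LDAModel-class]
#' @param X samples x features matrix (or a single sample vector)
#' @param components which discriminant components to keep (default all)
#' @return samples x components coordinate matrix `X V`
#' @export
ldaProject <- function(model, X, components = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != nrow(model@projection))
    stop("shape error: feature dimension mismatch (got ", ncol(X),
         ", model has ", nrow(model@projection), ")")
  V <- model@projection
  if (!is.null(components)) V <- V[, components, drop = FALSE]
  X %*% V
}

#' Binary discriminant score and class probability
#'
#' The signed score of a sample is the inner product between its projection
#' (relative to the midpoint of the two projected class means) and the
#' difference of projected class means; positive scores point to the first
#' class. The class probability is the logistic function of the score.
#'
#' @param model a two-class [LDAModel-class]
#' @param X samples x features matrix or single sample vector
#' @return data.frame with `score`, `prob` (probability of the first class),
#'   and `predicted` class label
#' @export
binaryDiscriminant <- function(model, X) {
  if (length(model@classes) != 2L)
    stop("binary-only error: model must have exactly 2 classes")
  Z <- ldaProject(model, X)
  mA <- drop(ldaProject(model, model@classMeans[1L, , drop = FALSE]))
  mB <- drop(ldaProject(model, model@classMeans[2L, , drop = FALSE]))
  mid <- (mA + mB) / 2
  score <- as.numeric(sweep(Z, 2L, mid) %*% (mA - mB))
  data.frame(score = score, prob = plogis(score),
             predicted = model@classes[ifelse(score >= 0, 1L, 2L)])
}

#' Multiclass class scores (negative distance to projected class means)
#'
#' @param model an [LDAModel-class]
#' @param X samples x features matrix
#' @return samples x classes matrix of scores (higher = closer)
#' @export
classScores <- function(model, X) {
  Z <- ldaProject(model, X)
  Mk <- ldaProject(model, model@classMeans)
  D2 <- outer(rowSums(Z^2), rowSums(Mk^2), "+") - 2 * Z %*% t(Mk)
  s <- -sqrt(pmax(D2, 0))
  colnames(s) <- model@classes
  s
}

#' Rank-based AUC with midrank tie handling
#'
#' Probability that the score of a positive-class sample exceeds that of a
#' negative-class sample (ties counted half).
#'
#' @param scores numeric scores
#' @param truth logical/0-1 vector (TRUE = positive class)
#' @return AUC in `[0, 1]`
#' @export
aucScore <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate evaluation: need scores from both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## one-vs-rest AUC averaged over classes present in the labels
multiclassAUC <- function(scoreMatrix, labels) {
  labels <- as.character(labels)
  present <- intersect(colnames(scoreMatrix), unique(labels))
  if (length(present) < 2L)
    stop("degenerate evaluation: need >= 2 classes present")
  mean(vapply(present, function(k)
    aucScore(scoreMatrix[, k], labels == k), numeric(1)))
}

#' Evaluate pooled held-out decoder outputs
#'
#' Computes rank-based AUC (binary mode), accuracy, balanced accuracy (mean
#' per-class recall), and normalized balanced accuracy
#' `(BA - 1/K) / (1 - 1/K)`, optionally with a row-normalized confusion
#' matrix (rows sum to 1, accommodating class imbalance).
#'
#' @param predicted predicted class labels
#' @param truth true class labels
#' @param scores binary mode: numeric score per sample for the positive
#'   class; multiclass mode: samples x classes score matrix (or `NULL` to
#'   skip AUC)
#' @param positive binary mode: label of the positive class (defaults to the
#'   first sorted label)
#' @param confusion return the row-normalized confusion matrix?
#' @return list of class `"DecodingResult"` with `auc`, `accuracy`,
#'   `balancedAccuracy`, `normalizedBA`, `chance`, `perClassRecall`, and
#'   optionally `confusion`
#' @export
evaluateDecoding <- function(predicted, truth, scores = NULL, positive = NULL,
                             confusion = FALSE) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(unique(truth))
  K <- length(classes)
  if (K < 2L) stop("degenerate evaluation: single-class labels")
  recall <- vapply(classes, function(k)
    mean(predicted[truth == k] == k), numeric(1))
  BA <- mean(recall)
  chance <- 1 / K
  auc <- NA_real_
  if (!is.null(scores)) {
    if (is.matrix(scores)) {
      auc <- multiclassAUC(scores, truth)
    } else {
      if (is.null(positive)) positive <- classes[1L]
      auc <- aucScore(scores, truth == positive)
    }
  }
  out <- list(auc = auc,
              accuracy = mean(predicted == truth),
              balancedAccuracy = BA,
              normalizedBA = (BA - chance) / (1 - chance),
              chance = chance,
              perClassRecall = recall)
  if (confusion) {
    cm <- table(factor(truth, classes), factor(predicted, sort(unique(c(classes, predicted)))))
    out$confusion <- sweep(unclass(cm), 1L, pmax(rowSums(cm), 1L), "/")
  }
  class(out) <- "DecodingResult"
  out
}

#' Cross-validation fold assignment
#'
#' `"loo"` assigns each sample its own fold; `"stratified"` builds `k` folds
#' preserving class proportions (each class's samples shuffled under the
#' seed, then dealt round-robin).
#'
#' @param labels class label per sample
#' @param strategy `"loo"` or `"stratified"`
#' @param k number of folds (stratified mode)
#' @param seed optional integer seed for reproducible fold assignment
#' @return integer fold id per sample
#' @export
cvFolds <- function(labels, strategy = c("loo", "stratified"), k = 5L,
                    seed = NULL) {
  strategy <- match.arg(strategy)
  n <- length(labels)
  if (strategy == "loo") return(seq_len(n))
  if (!is.null(seed)) set.seed(seed)
  f <- factor(labels)
  if (min(table(f)) < k)
    stop("fold error: k exceeds the smallest class count")
  fold <- integer(n)
  for (cl in levels(f)) {
    idx <- which(f == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated held-out scoring
#'
#' Generic cross-validation engine: every sample is scored exactly once by a
#' model never trained on it, and the per-fold outputs are pooled.
#'
#' @param X samples x features matrix
#' @param labels class label per sample
#' @param strategy,k,seed see [cvFolds()]
#' @param fitFun function(Xtrain, labelsTrain) -> model (default
#'   [fitDiagLDA()])
#' @param scoreFun function(model, Xtest) -> data.frame/matrix of per-sample
#'   outputs (default [binaryDiscriminant()])
#' @return list with pooled `scores` (rows in original sample order),
#'   `labels`, `folds`, and `nFits`
#' @export
crossValidate <- function(X, labels, strategy = "loo", k = 5L, seed = NULL,
                          fitFun = fitDiagLDA, scoreFun = binaryDiscriminant) {
  X <- as.matrix(X)
  fold <- cvFolds(labels, strategy, k = k, seed = seed)
  out <- NULL
  for (fd in sort(unique(fold))) {
    test <- fold == fd
    model <- fitFun(X[!test, , drop = FALSE], labels[!test])
    sc <- scoreFun(model, X[test, , drop = FALSE])
    sc <- as.data.frame(sc)
    if (is.null(out)) {
      out <- sc[rep(1L, length(fold)), , drop = FALSE]
      out[] <- NA
      rownames(out) <- NULL
    }
    out[test, ] <- sc
  }
  list(scores = out, labels = labels, folds = fold,
       nFits = length(unique(fold)))
}
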