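## Position-specific linear encoding of phoneme sequences:
##   y = b0 + p1' b1 + p2' b2 + p3' b3 + e
## with one-hot phoneme-by-position predictors and ridge regularization.
## The one-hot + intercept design is rank-deficient (each slot's block sums
## to the intercept column); ridge resolves the gauge, and the recoverable
## quantities are the zero-sum (within slot) coefficient contrasts, matching
## the generator's zero-sum convention.

#' Build the one-hot position x phoneme design matrix
#'
#' Deterministic column order: slot-major, inventory order within slot;
#' intercept last. Every covered slot contributes exactly one 1 per row.
#'
#' @param set a [ConditionSet-class]
#' @param labels integer condition indices (one per trial)
#' @param nSlots number of slots to encode (default: the set's maximum)
#' @return list with `X` (trials x (nSlots x inventory + 1) matrix, intercept
#'   last), and `columns` data.frame (`slot`, `phoneme`; the intercept row
#'   has slot 0)
#' @export
buildDesignMatrix <- function(set, labels, nSlots = NULL) {
  inv <- inventory(set)
  if (is.null(nSlots)) nSlots <- max(set@lengthClass)
  if (any(is.na(labels))) stop("label error: NA condition label")
  M <- length(inv)
  n <- length(labels)
  X <- matrix(0, n, nSlots * M + 1L)
  cols <- data.frame(slot = c(rep(seq_len(nSlots), each = M), 0L),
                     phoneme = c(rep(inv, nSlots), "(intercept)"),
                     stringsAsFactors = FALSE)
  for (p in seq_len(nSlots)) {
    cons <- slotConsonant(set, labels, p)
    j <- match(cons, inv)
    if (any(is.na(j) & !is.na(cons)))
      stop("label error: phoneme outside inventory")
    rows <- which(!is.na(j))
    X[cbind(rows, (p - 1L) * M + j[rows])] <- 1
  }
  X[, nSlots * M + 1L] <- 1
  colnames(X) <- paste0(ifelse(cols$slot > 0, paste0("C", cols$slot, "."), ""),
                        cols$phoneme)
  list(X = X, columns = cols)
}

## closed-form ridge with unpenalized intercept (intercept = last column)
ridgeSolve <- function(X, Y, alpha) {
  p <- ncol(X)
  pen <- diag(c(rep(alpha, p - 1L), 0), p)
  solve(crossprod(X) + pen, crossprod(X, Y))
}

#' Fit and cross-validate the phoneme-sequence encoding model
#'
#' Closed-form ridge regression (`alpha` on the summed squared coefficients,
#' intercept unpenalized) of window-averaged, z-scored activity on the
#' one-hot position x phoneme design. Held-out predictions are pooled over
#' stratified condition-balanced folds, and performance is reported as
#' single-trial R^2 (uniform average of per-feature R^2, so every electrode
#' counts equally) and condition-averaged R^2 on group means after
#' marginalizing over a set of slots (by default slot 1, i.e. conditions
#' defined by the later-position consonants).
#'
#' @param set a [ConditionSet-class]
#' @param labels integer condition index per trial
#' @param Y trials x features response matrix (z-scored activity, typically
#'   pre-filtered to significantly tuned features)
#' @param alpha ridge penalty (default 0.5)
#' @param nFolds stratified folds (default 3)
#' @param marginalizeSlots slots marginalized out of the condition-averaged
#'   R^2 grouping (default 1)
#' @param nBoot bootstrap resamples for the CI of both R^2 metrics (0
#'   disables)
#' @param nPerm label permutations for significance (0 disables)
#' @param seed optional integer seed (folds, bootstrap, permutation)
#' @return list with `model` (an [EncodingModel-class] refit on all trials),
#'   `singleTrialR2`, `conditionAveragedR2`, pooled `predictions`, fold ids,
#'   and optional `ci` / `permutation` components
#' @export
fitEncodingModel <- function(set, labels, Y, alpha = 0.5, nFolds = 3L,
                             marginalizeSlots = 1L, nBoot = 0L, nPerm = 0L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  des <- buildDesignMatrix(set, labels)
  X <- des$X
  if (min(table(labels)) < nFolds)
    stop("fold error: fewer trials than folds for some condition")

  heldOutPredictions <- function(lab) {
    Xl <- buildDesignMatrix(set, lab)$X
    fold <- cvFolds(lab, "stratified", k = nFolds)
    pred <- matrix(NA_real_, nrow(Y), ncol(Y))
    for (fd in seq_len(nFolds)) {
      test <- fold == fd
      beta <- ridgeSolve(Xl[!test, , drop = FALSE], Y[!test, , drop = FALSE], alpha)
      pred[test, ] <- Xl[test, , drop = FALSE] %*% beta
    }
    pred
  }

  r2Metrics <- function(pred, lab) {
    ## single-trial: uniform average over features of per-feature R^2
    sse <- colSums((Y - pred)^2)
    sst <- colSums(sweep(Y, 2L, colMeans(Y))^2)
    single <- mean(1 - sse / pmax(sst, .Machine$double.eps))
    ## condition-averaged: group means after marginalizing chosen slots
    key <- marginalKey(set, lab, marginalizeSlots)
    g <- factor(key)
    Gm <- rowsumMean(Y, g)
    Gp <- rowsumMean(pred, g)
    sseC <- colSums((Gm - Gp)^2)
    sstC <- colSums(sweep(Gm, 2L, colMeans(Gm))^2)
    condAvg <- mean(1 - sseC / pmax(sstC, .Machine$double.eps))
    c(single = single, condAvg = condAvg)
  }

  pred <- heldOutPredictions(labels)
  met <- r2Metrics(pred, labels)

  betaAll <- ridgeSolve(X, Y, alpha)
  p <- ncol(X)
  model <- new("EncodingModel",
               intercept = as.numeric(betaAll[p, ]),
               coef = t(betaAll[-p, , drop = FALSE]),
               columns = des$columns[-p, , drop = FALSE],
               alpha = alpha,
               residScale = apply(Y - X %*% betaAll, 2L, sd),
               featureMask = rep(TRUE, ncol(Y)))

  out <- list(model = model,
              singleTrialR2 = unname(met["single"]),
              conditionAveragedR2 = unname(met["condAvg"]),
              predictions = pred, labels = labels, alpha = alpha)

  if (nBoot > 0L) {
    ## resample pooled predictions (trials) with replacement
    idx <- seq_len(nrow(Y))
    stat <- function(ii) {
      sse <- colSums((Y[ii, , drop = FALSE] - pred[ii, , drop = FALSE])^2)
      sst <- colSums(sweep(Y[ii, , drop = FALSE], 2L,
                           colMeans(Y[ii, , drop = FALSE]))^2)
      mean(1 - sse / pmax(sst, .Machine$double.eps))
    }
    bb <- bootstrapCI(idx, stat, nBoot = nBoot)
    out$ci <- list(singleTrialR2 = c(bb$lower, bb$upper))
  }
  if (nPerm > 0L) {
    nullSingle <- numeric(nPerm); nullCond <- numeric(nPerm)
    for (r in seq_len(nPerm)) {
      lab <- labels[sample.int(length(labels))]
      m <- r2Metrics(heldOutPredictions(lab), lab)
      nullSingle[r] <- m["single"]; nullCond[r] <- m["condAvg"]
    }
    out$permutation <- list(
      pSingleTrial = mean(nullSingle >= met["single"]),
      pConditionAveraged = mean(nullCond >= met["condAvg"]),
      pFloor = 1 / nPerm)
  }
  out
}

## group key marginalizing given slots out of the condition labels
marginalKey <- function(set, labels, marginalizeSlots) {
  nSlots <- max(set@lengthClass)
  keep <- setdiff(seq_len(nSlots), marginalizeSlots)
  vapply(labels, function(i) {
    cons <- set@consonants[i, seq_len(set@lengthClass[i])]
    paste(ifelse(keep <= length(cons), cons[keep], "-"), collapse = ".")
  }, character(1))
}

rowsumMean <- function(Y, g) {
  s <- rowsum(Y, g)
  sweep(s, 1L, as.integer(table(g)[rownames(s)]), "/")
}

#' Cosine similarity of encoding coefficients across positions
#'
#' Computes the full cosine-similarity matrix over all (slot, phoneme)
#' coefficient vectors (vectors across features) of a model refit on all
#' trials, and summarizes each slot pair as the mean cosine over
#' like-phoneme pairs (e.g. /K/ at C1 vs /K/ at C2). Optional permutation
#' significance (labels shuffled, model refit) and bootstrap CI (trials
#' resampled, model refit) for the summaries.
#'
#' @param set,labels,Y,alpha as in [fitEncodingModel()]
#' @param nPerm label permutations (0 disables)
#' @param nBoot trial resamples (0 disables)
#' @param seed optional integer seed
#' @return list with `cosine` (full matrix, `NA` where a coefficient vector
#'   is zero), `summary` data.frame (slotA, slotB, meanCosine, and optional
#'   p / CI columns)
#' @export
coefficientSimilarity <- function(set, labels, Y, alpha = 0.5, nPerm = 0L,
                                  nBoot = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  des <- buildDesignMatrix(set, labels)
  cols <- des$columns
  pred <- which(cols$slot > 0)
  fitCoef <- function(lab, rows = seq_len(nrow(Y))) {
    Xl <- buildDesignMatrix(set, lab[rows])$X
    beta <- ridgeSolve(Xl, Y[rows, , drop = FALSE], alpha)
    t(beta[pred, , drop = FALSE])               # features x predictors
  }
  cosMat <- function(B) {
    nrm <- sqrt(colSums(B^2))
    C <- crossprod(B) / outer(nrm, nrm)
    C[, nrm == 0] <- NA; C[nrm == 0, ] <- NA
    C
  }
  likeSummary <- function(C) {
    slots <- sort(unique(cols$slot[pred]))
    out <- list()
    for (a in slots) for (b in slots) {
      if (b <= a) next
      ph <- unique(cols$phoneme[pred])
      vals <- vapply(ph, function(q) {
        ia <- which(cols$slot[pred] == a & cols$phoneme[pred] == q)
        ib <- which(cols$slot[pred] == b & cols$phoneme[pred] == q)
        C[ia, ib]
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(slotA = a, slotB = b,
                                            meanCosine = mean(vals, na.rm = TRUE))
    }
    do.call(rbind, out)
  }
  B <- fitCoef(labels)
  C <- cosMat(B)
  dimnames(C) <- list(colnames(des$X)[pred], colnames(des$X)[pred])
  summary <- likeSummary(C)
  out <- list(cosine = C, summary = summary)
  if (nPerm > 0L) {
    null <- replicate(nPerm,
      likeSummary(cosMat(fitCoef(labels[sample.int(length(labels))])))$meanCosine)
    null <- matrix(null, nrow = nrow(summary))
    out$summary$p <- vapply(seq_len(nrow(summary)), function(i)
      mean(null[i, ] >= summary$meanCosine[i]), numeric(1))
    out$pFloor <- 1 / nPerm
  }
  if (nBoot > 0L) {
    n <- nrow(Y)
    draws <- replicate(nBoot, {
      rows <- sample.int(n, n, replace = TRUE)
      likeSummary(cosMat(fitCoef(labels, rows)))$meanCosine
    })
    draws <- matrix(draws, nrow = nrow(summary))
    out$summary$ciLower <- apply(draws, 1L, quantile, 0.025, na.rm = TRUE)
    out$summary$ciUpper <- apply(draws, 1L, quantile, 0.975, na.rm = TRUE)
  }
  out
}
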