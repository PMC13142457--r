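## Figure-level decoding experiments: per-position pairwise decoding,
## cross-time and cross-epoch decoder generalization, cross-position
## generalization, sequence-length decoding, and the word-boundary analyses.
## Every analysis consumes only held-out scores.

condClass <- function(labels) sprintf("c%04d", labels)

## one-sided t-test p-values that tolerate degenerate (constant) inputs
safeT1 <- function(x, mu, alternative = "greater") {
  if (length(x) < 2L || sd(x) == 0) return(NA_real_)
  stats::t.test(x, mu = mu, alternative = alternative)$p.value
}
safeT2 <- function(x, y, alternative = "greater") {
  if (length(x) < 2L || length(y) < 2L || (sd(x) == 0 && sd(y) == 0))
    return(NA_real_)
  stats::t.test(x, y, alternative = alternative)$p.value
}

## binary diag-LDA over one condition pair with pooled held-out
## probabilities for the pair's FIRST condition
pairScores <- function(X, labels, pair, strategy = "loo", k = 5L) {
  rows <- which(labels %in% pair)
  lab <- condClass(labels[rows])
  pos <- condClass(pair[1])
  cv <- crossValidate(X[rows, , drop = FALSE], lab, strategy = strategy, k = k)
  ## binaryDiscriminant's positive class is the model's first (sorted) class;
  ## re-orient the probability toward `pos`
  prob <- cv$scores$prob
  if (sort(unique(lab))[1] != pos) prob <- 1 - prob
  list(prob = prob, truth = lab == pos, rows = rows)
}

#' Pairwise single-position decoding
#'
#' Fits one binary diagonal-LDA decoder per single-position difference pair
#' (leave-one-out, held-out probabilities pooled per pair), reports the AUC
#' per pair and their mean, a bootstrap CI (trials resampled within pair),
#' and a one-sided one-sample t-test of the per-pair AUCs against chance.
#'
#' @param session a [SessionData-class] (z-score first)
#' @param position consonant slot the pairs differ at
#' @param window an [epochWindow()] for the averaged feature window
#' @param slide optional `list(widthMs=, stepMs=)`; when given, the analysis
#'   is repeated for sliding windows spanning `window` and a time course of
#'   mean AUC is returned instead
#' @param nBoot bootstrap resamples for the CI of the mean AUC (0 disables)
#' @param minTrialsPerCondition pairs with fewer trials in either condition
#'   are skipped
#' @param maxPairs optional cap on the number of pairs (subsampled under the
#'   current RNG); `Inf` uses all
#' @param cv cross-validation strategy per pair: `"loo"` (the default for
#'   pairwise decoding) or `"stratified"` k-fold, which carries a smaller
#'   finite-sample pessimistic bias on signal-free data
#' @param k folds for the stratified strategy
#' @return list with `meanAUC`, `perPair` (data.frame), `p` (t-test vs 0.5),
#'   `ci`, `nPairs`; in sliding mode `time` and `meanAUC` vectors
#' @export
pairwisePositionDecoding <- function(session, position, window, slide = NULL,
                                     nBoot = 0L, minTrialsPerCondition = 2L,
                                     maxPairs = Inf, cv = "loo", k = 5L) {
  set <- conditionSet(session)
  pairs <- singlePositionPairs(set, position)
  if (is.finite(maxPairs) && nrow(pairs) > maxPairs)
    pairs <- pairs[sort(sample.int(nrow(pairs), maxPairs)), , drop = FALSE]

  if (!is.null(slide)) {
    ext <- extractWindows(session, window, mode = "sliding",
                          widthMs = slide$widthMs, stepMs = slide$stepMs)
    auc <- vapply(ext$windows, function(w)
      pairwiseAUCOnMatrix(w$matrix, trialLabels(session)[w$trials],
                          pairs, minTrialsPerCondition,
                          strategy = cv, k = k)$meanAUC, numeric(1))
    return(list(time = ext$starts, meanAUC = auc, alignEvent = window$alignEvent))
  }

  ext <- extractWindows(session, window, mode = "average")
  res <- pairwiseAUCOnMatrix(ext$matrix, trialLabels(session)[ext$trials],
                             pairs, minTrialsPerCondition, keepScores = TRUE,
                             strategy = cv, k = k)
  aucs <- res$perPair$auc
  tt <- safeT1(aucs, 0.5)
  out <- list(meanAUC = res$meanAUC, perPair = res$perPair, p = tt,
              nPairs = nrow(res$perPair))
  if (nBoot > 0L) {
    draws <- vapply(seq_len(nBoot), function(r) {
      mean(vapply(res$scores, function(s) {
        for (try in 1:100) {
          ii <- sample.int(length(s$prob), replace = TRUE)
          if (length(unique(s$truth[ii])) == 2L)
            return(aucScore(s$prob[ii], s$truth[ii]))
        }
        aucScore(s$prob, s$truth)
      }, numeric(1)))
    }, numeric(1))
    out$ci <- unname(quantile(draws, c(0.025, 0.975)))
  }
  out
}

pairwiseAUCOnMatrix <- function(X, labels, pairs, minTrialsPerCondition = 2L,
                                keepScores = FALSE, strategy = "loo", k = 5L) {
  perPair <- list(); scores <- list()
  for (r in seq_len(nrow(pairs))) {
    pr <- pairs[r, ]
    n1 <- sum(labels == pr[1], na.rm = TRUE)
    n2 <- sum(labels == pr[2], na.rm = TRUE)
    if (n1 < minTrialsPerCondition || n2 < minTrialsPerCondition) next
    ps <- pairScores(X, labels, pr, strategy = strategy, k = k)
    perPair[[length(perPair) + 1L]] <-
      data.frame(a = pr[1], b = pr[2], auc = aucScore(ps$prob, ps$truth),
                 n = n1 + n2)
    if (keepScores) scores[[length(scores) + 1L]] <- ps
  }
  if (!length(perPair)) stop("design error: no qualifying pairs")
  perPair <- do.call(rbind, perPair)
  list(meanAUC = mean(perPair$auc), perPair = perPair, scores = scores)
}

#' Cross-time decoder generalization matrix
#'
#' Trains a binary decoder per pair at every fit time (sliding windows
#' across the trial span) under leave-one-out cross-validation; each
#' held-out trial is scored at every valid test time, probabilities are
#' pooled per (fit, test) cell, and AUC is averaged over pairs. Fit times
#' whose window is covered by fewer than `minTrials` labeled trials are
#' masked (reported, never silently dropped).
#'
#' @param session a [SessionData-class]
#' @param position consonant slot the pairs differ at
#' @param window an [epochWindow()] spanning the analysis range
#' @param widthMs,stepMs sliding-window geometry
#' @param minTrials minimum labeled trials covering a fit window (the
#'   field-standard default of 900 suits large sessions; set lower for
#'   small synthetic sessions)
#' @param maxPairs optional cap on pairs
#' @return list with `time` (window starts), `auc` (fit x test matrix),
#'   `mask` (fit times failing `minTrials`), `nTrials` per window
#' @export
crossTimeGeneralization <- function(session, position, window,
                                    widthMs = 100, stepMs = 60,
                                    minTrials = 900L, maxPairs = Inf) {
  set <- conditionSet(session)
  pairs <- singlePositionPairs(set, position)
  if (is.finite(maxPairs) && nrow(pairs) > maxPairs)
    pairs <- pairs[sort(sample.int(nrow(pairs), maxPairs)), , drop = FALSE]
  ext <- extractWindows(session, window, mode = "sliding",
                        widthMs = widthMs, stepMs = stepMs)
  nW <- length(ext$starts)
  labAll <- trialLabels(session)
  nCover <- vapply(ext$windows, function(w) length(w$trials), integer(1))
  mask <- nCover < minTrials

  sumNum <- matrix(0, nW, nW)   # accumulated AUC over pairs
  cnt <- matrix(0, nW, nW)
  for (r in seq_len(nrow(pairs))) {
    pr <- pairs[r, ]
    ## probs[[f]][[t]] pooled over held-out trials
    probs <- vector("list", nW); truths <- vector("list", nW)
    for (f in seq_len(nW)) {
      if (mask[f]) next
      wf <- ext$windows[[f]]
      rows <- which(labAll[wf$trials] %in% pr)
      if (length(rows) < 4L) next
      trialIds <- wf$trials[rows]
      Xf <- wf$matrix[rows, , drop = FALSE]
      lab <- condClass(labAll[trialIds])
      pos <- condClass(pr[1])
      flip <- sort(unique(lab))[1] != pos
      pf <- matrix(NA_real_, length(rows), nW)
      for (i in seq_along(rows)) {
        model <- fitDiagLDA(Xf[-i, , drop = FALSE], lab[-i])
        ## score the held-out trial at every test time it covers
        testX <- matrix(NA_real_, nW, ncol(Xf))
        has <- logical(nW)
        for (tt in seq_len(nW)) {
          wt <- ext$windows[[tt]]
          j <- match(trialIds[i], wt$trials)
          if (!is.na(j)) { testX[tt, ] <- wt$matrix[j, ]; has[tt] <- TRUE }
        }
        if (any(has)) {
          bd <- binaryDiscriminant(model, testX[has, , drop = FALSE])
          pf[i, has] <- if (flip) 1 - bd$prob else bd$prob
        }
      }
      for (tt in seq_len(nW)) {
        ok <- !is.na(pf[, tt])
        if (sum(ok) < 2L || length(unique(lab[ok])) < 2L) next
        a <- aucScore(pf[ok, tt], lab[ok] == pos)
        sumNum[f, tt] <- sumNum[f, tt] + a
        cnt[f, tt] <- cnt[f, tt] + 1
      }
    }
  }
  auc <- sumNum / cnt
  auc[cnt == 0] <- NA_real_
  list(time = ext$starts, auc = auc, mask = mask, nTrials = nCover,
       alignEvent = window$alignEvent)
}

## mean within-window (train = test) pairwise AUC time course
withinTimeSweep <- function(session, position, window, widthMs, stepMs,
                            maxPairs = Inf) {
  res <- pairwisePositionDecoding(session, position, window,
                                  slide = list(widthMs = widthMs, stepMs = stepMs),
                                  maxPairs = maxPairs)
  res
}

#' Cross-epoch decoder generalization
#'
#' Anchors a 0.5 s cue window on the cue-epoch peak decoding time and a
#' 0.5 s speech window on the speech-epoch peak (peaks found by a
#' within-window sliding sweep; first bin on ties), takes the 0.5 s
#' immediately preceding the go cue as the preparatory window, then trains
#' binary decoders per pair on cue-window features (leave-one-out) and
#' tests each held-out trial on all three epoch windows.
#'
#' @param session a [SessionData-class]
#' @param position consonant slot the pairs differ at
#' @param cueSpan,speechSpan [epochWindow()]s swept for the peaks (defaults:
#'   the audio cue from onset, and 0.5 s around speech onset)
#' @param widthMs,stepMs sweep geometry
#' @param windowS epoch-window length in seconds
#' @param maxPairs optional cap on pairs
#' @return list with `auc` (named: cue, prep, speech), `peaks` (seconds,
#'   named cue/speech), per-pair detail
#' @export
crossEpochGeneralization <- function(session, position,
                                     cueSpan = NULL, speechSpan = NULL,
                                     widthMs = 100, stepMs = 60,
                                     windowS = 0.5, maxPairs = Inf) {
  ev <- trialEvents(session)
  cueDur <- min(ev$cue_offset - ev$cue_onset, na.rm = TRUE)
  if (is.null(cueSpan)) cueSpan <- epochWindow("cue_onset", 0, cueDur)
  if (is.null(speechSpan)) speechSpan <- epochWindow("speech_onset", -0.5, 0.5)

  sweepCue <- withinTimeSweep(session, position, cueSpan, widthMs, stepMs, maxPairs)
  sweepSpe <- withinTimeSweep(session, position, speechSpan, widthMs, stepMs, maxPairs)
  peakCue <- sweepCue$time[which.max(sweepCue$meanAUC)]
  peakSpe <- sweepSpe$time[which.max(sweepSpe$meanAUC)]
  half <- windowS / 2
  width <- widthMs / 1000
  ## center the epoch window on the peak window's center, shifted if needed
  ## to stay inside the swept span
  centered <- function(event, center, lo, hi) {
    s <- center - half; e <- center + half
    if (s < lo) { e <- e + (lo - s); s <- lo }
    if (e > hi) { s <- s - (e - hi); e <- hi }
    epochWindow(event, s, e)
  }
  wins <- list(
    cue = centered("cue_onset", peakCue + width / 2, cueSpan$start, cueSpan$end),
    prep = epochWindow("go_cue", -windowS, 0),
    speech = centered("speech_onset", peakSpe + width / 2,
                      speechSpan$start, speechSpan$end))

  exts <- lapply(wins, function(w) extractWindows(session, w, mode = "average"))
  common <- Reduce(intersect, lapply(exts, `[[`, "trials"))
  mats <- lapply(exts, function(e)
    e$matrix[match(common, e$trials), , drop = FALSE])
  labAll <- trialLabels(session)[common]

  set <- conditionSet(session)
  pairs <- singlePositionPairs(set, position)
  if (is.finite(maxPairs) && nrow(pairs) > maxPairs)
    pairs <- pairs[sort(sample.int(nrow(pairs), maxPairs)), , drop = FALSE]
  perPair <- list()
  for (r in seq_len(nrow(pairs))) {
    pr <- pairs[r, ]
    rows <- which(labAll %in% pr)
    if (length(rows) < 4L) next
    lab <- condClass(labAll[rows])
    pos <- condClass(pr[1])
    flip <- sort(unique(lab))[1] != pos
    probs <- matrix(NA_real_, length(rows), 3L,
                    dimnames = list(NULL, names(wins)))
    for (i in seq_along(rows)) {
      model <- fitDiagLDA(mats$cue[rows[-i], , drop = FALSE], lab[-i])
      for (e in names(wins)) {
        bd <- binaryDiscriminant(model, mats[[e]][rows[i], ])
        probs[i, e] <- if (flip) 1 - bd$prob else bd$prob
      }
    }
    perPair[[length(perPair) + 1L]] <- data.frame(
      a = pr[1], b = pr[2],
      cue = aucScore(probs[, "cue"], lab == pos),
      prep = aucScore(probs[, "prep"], lab == pos),
      speech = aucScore(probs[, "speech"], lab == pos))
  }
  if (!length(perPair)) stop("design error: no qualifying pairs")
  perPair <- do.call(rbind, perPair)
  list(auc = c(cue = mean(perPair$cue), prep = mean(perPair$prep),
               speech = mean(perPair$speech)),
       peaks = c(cue = peakCue, speech = peakSpe),
       perPair = perPair)
}

#' Cross-position decoder generalization
#'
#' Trains a multiclass diagonal-LDA decoder on consonant identity at one
#' position (stratified 5-fold), then evaluates the pooled held-out class
#' scores both in-context (against the training position's labels) and
#' out-of-context (relabeling each held-out trial by its consonant at the
#' test position), with one-vs-rest AUC averaged over the shared inventory.
#' Generalization is normalized as `(AUCcross - 0.5) / (AUCwithin - 0.5)`.
#'
#' @param session a [SessionData-class]
#' @param trainPosition,testPosition consonant slots
#' @param window an [epochWindow()] (default: 0.7 s preparatory window)
#' @param k stratified folds
#' @param nBoot bootstrap resamples over held-out trials for the CI
#' @param seed optional integer seed (folds, bootstrap)
#' @return list of class `"GeneralizationResult"`: `aucWithin`, `aucCross`,
#'   `normalizedGeneralization`, optional `ci`
#' @export
crossPositionGeneralization <- function(session, trainPosition, testPosition,
                                        window = epochWindow("go_cue", -0.7, 0),
                                        k = 5L, nBoot = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  set <- conditionSet(session)
  ext <- extractWindows(session, window, mode = "average")
  labs <- trialLabels(session)[ext$trials]
  trainLab <- slotConsonant(set, labs, trainPosition)
  testLab <- slotConsonant(set, labs, testPosition)
  ok <- !is.na(trainLab) & !is.na(testLab)
  if (!any(ok))
    stop("label error: no trials carry consonants at both positions")
  if (!setequal(unique(trainLab[ok]), unique(testLab[ok])))
    stop("label error: positions do not share a consonant inventory")
  X <- ext$matrix[ok, , drop = FALSE]
  trainLab <- trainLab[ok]; testLab <- testLab[ok]
  cv <- crossValidate(X, trainLab, strategy = "stratified", k = k,
                      scoreFun = classScores)
  S <- as.matrix(cv$scores)
  colnames(S) <- sort(unique(trainLab))
  within <- multiclassAUC(S, trainLab)
  cross <- multiclassAUC(S, testLab)
  norm <- (cross - 0.5) / (within - 0.5)
  out <- list(aucWithin = within, aucCross = cross,
              normalizedGeneralization = norm)
  if (nBoot > 0L) {
    n <- nrow(S)
    draws <- vapply(seq_len(nBoot), function(r) {
      ii <- sample.int(n, n, replace = TRUE)
      w <- tryCatch(multiclassAUC(S[ii, , drop = FALSE], trainLab[ii]),
                    error = function(e) NA_real_)
      cr <- tryCatch(multiclassAUC(S[ii, , drop = FALSE], testLab[ii]),
                     error = function(e) NA_real_)
      (cr - 0.5) / (w - 0.5)
    }, numeric(1))
    out$ci <- unname(quantile(draws, c(0.025, 0.975), na.rm = TRUE))
  }
  class(out) <- "GeneralizationResult"
  out
}

#' Sequence-length decoding
#'
#' Multiclass diagonal LDA on sequence-length classes over a preparatory
#' window (stratified 5-fold), reported as normalized balanced accuracy
#' `(BA - 1/K) / (1 - 1/K)` with a one-tailed label-shuffling permutation
#' test in which the full cross-validation is repeated per shuffle.
#'
#' @param session a [SessionData-class] built on a mixed-length set
#' @param window an [epochWindow()] (default: 0.6 s preparatory window)
#' @param k stratified folds
#' @param nPerm permutations (0 disables)
#' @param seed optional integer seed
#' @return list with `normalizedBA`, `balancedAccuracy`, `chance`,
#'   `confusion`, optional `permutation`
#' @export
sequenceLengthDecoding <- function(session, window = epochWindow("go_cue", -0.6, 0),
                                   k = 5L, nPerm = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  set <- conditionSet(session)
  ext <- extractWindows(session, window, mode = "average")
  labs <- trialLabels(session)[ext$trials]
  lenLab <- as.character(set@lengthClass[labs])
  if (length(unique(lenLab)) < 2L)
    stop("design error: need >= 2 length classes")
  X <- ext$matrix
  runCV <- function(lab) {
    cv <- crossValidate(X, lab, strategy = "stratified", k = k,
                        scoreFun = classScores)
    S <- as.matrix(cv$scores)
    cls <- sort(unique(lab))
    pred <- cls[max.col(S, ties.method = "first")]
    evaluateDecoding(pred, lab, scores = S, confusion = TRUE)
  }
  res <- runCV(lenLab)
  out <- list(normalizedBA = res$normalizedBA,
              balancedAccuracy = res$balancedAccuracy,
              chance = res$chance, confusion = res$confusion)
  if (nPerm > 0L) {
    null <- vapply(seq_len(nPerm), function(r)
      runCV(sample(lenLab))$normalizedBA, numeric(1))
    out$permutation <- list(p = mean(null >= res$normalizedBA),
                            pFloor = 1 / nPerm, null = null)
  }
  out
}

#' Word-boundary analyses
#'
#' Two analyses on a matched one-/two-word condition set: (a) a boundary
#' classifier (one vs two words, all sequences pooled) on the preparatory
#' window with k-fold cross-validation stratified by phoneme sequence, AUC
#' averaged across folds with a normal-approximation CI (+/- 1.96 sd over
#' folds); (b) for every condition pair sharing the first two consonant
#' slots and differing in the third and/or fourth, binary decoders fit
#' separately within the one-word and two-word contexts (leave-one-out),
#' AUC averaged per context, and the context difference tested by a
#' one-sided two-sample t-test over pairs.
#'
#' @param session a [SessionData-class] built on [buildWordBoundarySet()]
#' @param window an [epochWindow()] (default: 0.5 s preparatory window)
#' @param kBoundary folds for the boundary classifier
#' @param sharedSlots slots that late-position pairs must share
#' @param maxPairs optional cap on late-position pairs per context
#' @param seed optional integer seed
#' @return list with `boundary` (foldAUCs, meanAUC, ci, p) and
#'   `latePosition` (aucOneWord, aucTwoWord, deltaAUC, pOneWord, pTwoWord,
#'   pDelta, per-pair detail)
#' @export
wordBoundaryAnalysis <- function(session, window = epochWindow("go_cue", -0.5, 0),
                                 kBoundary = 10L, sharedSlots = 1:2,
                                 maxPairs = Inf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  set <- conditionSet(session)
  isTwo <- vapply(set@segmentation, length, integer(1)) > 0L
  if (!any(isTwo) || all(isTwo))
    stop("design error: set must contain one-word and two-word conditions")
  ext <- extractWindows(session, window, mode = "average")
  labs <- trialLabels(session)[ext$trials]
  X <- ext$matrix
  boundary <- ifelse(isTwo[labs], "two", "one")
  seqKey <- apply(set@consonants[labs, , drop = FALSE], 1L, paste, collapse = ".")

  ## (a) boundary classifier, folds stratified by sequence x context:
  ## each group's trials are dealt round-robin from a random offset, so
  ## groups smaller than k still spread evenly
  strat <- paste(seqKey, boundary)
  fold <- integer(length(strat))
  for (g in unique(strat)) {
    idx <- which(strat == g)
    idx <- idx[sample.int(length(idx))]
    off <- sample.int(kBoundary, 1L)
    fold[idx] <- ((seq_along(idx) - 1L + off) %% kBoundary) + 1L
  }
  foldAUC <- vapply(seq_len(kBoundary), function(fd) {
    test <- fold == fd
    model <- fitDiagLDA(X[!test, , drop = FALSE], boundary[!test])
    bd <- binaryDiscriminant(model, X[test, , drop = FALSE])
    prob <- if (model@classes[1] == "one") bd$prob else 1 - bd$prob
    aucScore(prob, boundary[test] == "one")
  }, numeric(1))
  bMean <- mean(foldAUC)
  bSd <- sd(foldAUC)
  bP <- safeT1(foldAUC, 0.5)
  boundaryRes <- list(foldAUCs = foldAUC, meanAUC = bMean,
                      ci = c(bMean - 1.96 * bSd, bMean + 1.96 * bSd), p = bP)

  ## (b) late-position pairs within each context
  ctxAUC <- function(segmented) {
    pairs <- latePositionPairs(set, sharedSlots = sharedSlots,
                               segmented = segmented)
    if (is.finite(maxPairs) && nrow(pairs) > maxPairs)
      pairs <- pairs[sort(sample.int(nrow(pairs), maxPairs)), , drop = FALSE]
    pairwiseAUCOnMatrix(X, labs, pairs)
  }
  one <- ctxAUC(FALSE)
  two <- ctxAUC(TRUE)
  tOne <- safeT1(one$perPair$auc, 0.5)
  tTwo <- safeT1(two$perPair$auc, 0.5)
  pDelta <- safeT2(one$perPair$auc, two$perPair$auc)
  list(boundary = boundaryRes,
       latePosition = list(aucOneWord = one$meanAUC, aucTwoWord = two$meanAUC,
                           deltaAUC = two$meanAUC - one$meanAUC,
                           pOneWord = tOne, pTwoWord = tTwo, pDelta = pDelta,
                           perPairOneWord = one$perPair,
                           perPairTwoWord = two$perPair))
}

#' Return a session with trial labels randomly permuted
#'
#' A leakage sentinel: running any analysis on a label-shuffled session
#' must produce chance-level output.
#'
#' @param session a [SessionData-class]
#' @param seed optional integer seed
#' @return the permuted [SessionData-class]
#' @export
permuteLabels <- function(session, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  session@labels <- session@labels[sample.int(nTrials(session))]
  session
}
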