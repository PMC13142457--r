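## Displacement-vector representational geometry: wildcard marginal means,
## displacement vectors between nested groupings, the leave-one-condition-out
## compositional predictor, best-fit 2-D planes, and marginal correlation
## matrices. Operations run on any coordinate matrix (discriminant-component
## space or full feature space); the space is the caller's choice.

#' Marginal (wildcard-grouped) condition means
#'
#' Groups points by the consonant identities at a subset of slots,
#' marginalizing (averaging) over all others — e.g. keeping slot 3 only
#' groups `*ah*ahSH`-style conditions. Keeping no slot yields the grand
#' mean; keeping all slots yields per-condition means.
#'
#' @param points trials x coordinates matrix
#' @param set a [ConditionSet-class]
#' @param labels integer condition index per row of `points`
#' @param keepSlots integer vector of slots kept as grouping factors
#'   (wildcards everywhere else); `integer(0)` for the grand mean
#' @return list of class `"MarginalMeanSet"` with `means` (groups x coords),
#'   `keys` (data.frame of kept-slot consonants), `counts`, `keepSlots`;
#'   empty groups are reported in `emptyGroups` and excluded
#' @export
marginalMeans <- function(points, set, labels, keepSlots) {
  points <- as.matrix(points)
  keepSlots <- as.integer(keepSlots)
  maxSlots <- max(set@lengthClass)
  if (length(keepSlots) && (min(keepSlots) < 1L || max(keepSlots) > maxSlots))
    stop("pattern inconsistent with label template")
  key <- if (length(keepSlots) == 0L) rep("(all)", length(labels)) else
    apply(do.call(cbind, lapply(keepSlots, function(p)
      slotConsonant(set, labels, p))), 1L, paste, collapse = ".")
  ok <- !is.na(labels) & !grepl("NA", key, fixed = TRUE)
  g <- factor(key[ok])
  means <- rowsumMean(points[ok, , drop = FALSE], g)
  counts <- as.integer(table(g)[rownames(means)])
  keys <- if (length(keepSlots)) {
    kd <- do.call(rbind, strsplit(rownames(means), ".", fixed = TRUE))
    kd <- as.data.frame(kd, stringsAsFactors = FALSE)
    names(kd) <- paste0("C", keepSlots)
    kd
  } else data.frame(row.names = "(all)")
  structure(list(means = means, keys = keys, counts = counts,
                 keepSlots = keepSlots, emptyGroups = character(0)),
            class = "MarginalMeanSet")
}

#' Displacement vectors between nested marginal groupings
#'
#' For each refined group (e.g. `*ahNahSH`), subtracts the mean of its
#' enclosing base group (e.g. `*ah*ahSH`): the displacement encodes the
#' refined factor's contribution as a direction in state space. The base
#' grouping's kept slots must be a subset of the refined grouping's. On
#' balanced designs the count-weighted displacements sum to zero within
#' each base group.
#'
#' @param base,refined `"MarginalMeanSet"` objects from [marginalMeans()]
#' @return list of class `"DisplacementSet"` with `vectors` (refined groups
#'   x coords), `refinedKeys`, `baseKey` (the enclosing base group per
#'   vector), `counts`
#' @export
displacementVectors <- function(base, refined) {
  if (!all(base$keepSlots %in% refined$keepSlots))
    stop("grouping error: base grouping must nest inside refined grouping")
  baseKey <- if (length(base$keepSlots) == 0L)
    rep("(all)", nrow(refined$means))
  else apply(refined$keys[, paste0("C", base$keepSlots), drop = FALSE],
             1L, paste, collapse = ".")
  i <- match(baseKey, rownames(base$means))
  if (anyNA(i)) stop("grouping error: refined group without base group")
  structure(list(vectors = refined$means - base$means[i, , drop = FALSE],
                 refinedKeys = refined$keys, baseKey = baseKey,
                 counts = refined$counts),
            class = "DisplacementSet")
}

#' Fraction of variance captured by the best-fit 2-D plane
#'
#' Mean-centers a point set, takes the top two right-singular directions,
#' and reports the captured fraction of total variance.
#'
#' @param points groups x coordinates matrix (>= 3 points)
#' @return scalar fraction in `[0, 1]`
#' @export
planeVariance2D <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("degenerate: need >= 3 points")
  Xc <- sweep(points, 2L, colMeans(points))
  sv <- svd(Xc)$d
  tot <- sum(sv^2)
  if (tot == 0) return(1)
  sum(sv[seq_len(min(2L, length(sv)))]^2) / tot
}

#' Leave-one-condition-out compositional prediction
#'
#' Tests whether class means (sequence-length x first-consonant classes in
#' discriminant space) are compositional: each held-out class mean is
#' predicted as the sum of its sequence-length mean and a phoneme
#' displacement vector donated by the other sequence lengths, scaled by the
#' ratio of mean displacement norms between target and donor lengths, and
#' averaged over donor lengths. R^2 is computed as a single multivariate
#' statistic (sums of squares pooled over components, which weights each
#' component by its variance) for condition-averaged and single-trial data.
#'
#' @param points trials x coordinates matrix (typically discriminant
#'   projections of held-out trials)
#' @param lengths per-trial sequence-length class
#' @param phonemes per-trial first-consonant identity
#' @param scale use the displacement-norm-ratio scaling (`TRUE`) or donate
#'   displacements unscaled
#' @param donors optional fixed donor length set (default: all other
#'   lengths; supplying the target's own length reproduces the class mean
#'   exactly, a self-consistency check)
#' @param nBoot bootstrap resamples over conditions/trials for CIs
#' @param nPerm label permutations (labels shuffled before displacement
#'   estimation) for significance
#' @param seed optional integer seed
#' @return list with `conditionAveragedR2`, `singleTrialR2`, `predicted`
#'   and `observed` class-mean matrices, class `keys`, and optional `ci` /
#'   `permutation` entries
#' @export
compositionalPredict <- function(points, lengths, phonemes, scale = TRUE,
                                 donors = NULL, nBoot = 0L, nPerm = 0L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  points <- as.matrix(points)
  lengths <- as.character(lengths); phonemes <- as.character(phonemes)
  lenLevels <- sort(unique(lengths))
  if (length(lenLevels) < 2L && is.null(donors))
    stop("design error: need >= 2 length classes")

  predictMeans <- function(pts, len, pho) {
    key <- paste(len, pho, sep = "|")
    classMean <- rowsumMean(pts, factor(key))
    lenMean <- rowsumMean(pts, factor(len))
    keys <- do.call(rbind, strsplit(rownames(classMean), "|", fixed = TRUE))
    kl <- keys[, 1]; kp <- keys[, 2]
    disp <- classMean - lenMean[kl, , drop = FALSE]
    pred <- matrix(NA_real_, nrow(classMean), ncol(classMean),
                   dimnames = dimnames(classMean))
    for (i in seq_len(nrow(classMean))) {
      L0 <- kl[i]; ph0 <- kp[i]
      donorLens <- if (is.null(donors)) setdiff(unique(kl), L0) else donors
      ## target-length displacement magnitude estimated from the OTHER
      ## phonemes (the held-out class never informs its own prediction)
      ownRows <- kl == L0 & kp != ph0
      contribs <- lapply(donorLens, function(Ld) {
        j <- which(kl == Ld & kp == ph0)
        if (!length(j)) return(NULL)
        d <- disp[j, ]
        if (scale && !identical(Ld, L0)) {
          numer <- mean(sqrt(rowSums(disp[ownRows, , drop = FALSE]^2)))
          denom <- mean(sqrt(rowSums(disp[kl == Ld & kp != ph0, , drop = FALSE]^2)))
          if (denom > 0) d <- d * numer / denom
        }
        d
      })
      contribs <- contribs[!vapply(contribs, is.null, logical(1))]
      if (!length(contribs)) next
      pred[i, ] <- lenMean[L0, ] + colMeans(do.call(rbind, contribs))
    }
    list(pred = pred, obs = classMean, kl = kl, kp = kp)
  }

  multivariateR2 <- function(obs, pred, center = colMeans(obs)) {
    ok <- !is.na(pred[, 1])
    sse <- sum((obs[ok, ] - pred[ok, ])^2)
    sst <- sum(sweep(obs[ok, , drop = FALSE], 2L, center)^2)
    1 - sse / max(sst, .Machine$double.eps)
  }

  pm <- predictMeans(points, lengths, phonemes)
  condR2 <- multivariateR2(pm$obs, pm$pred)
  ## single-trial: each trial compared with its class's prediction
  key <- paste(lengths, phonemes, sep = "|")
  trialPred <- pm$pred[match(key, rownames(pm$pred)), , drop = FALSE]
  okT <- !is.na(trialPred[, 1])
  sseT <- sum((points[okT, ] - trialPred[okT, ])^2)
  sstT <- sum(sweep(points[okT, , drop = FALSE], 2L,
                    colMeans(points[okT, , drop = FALSE]))^2)
  singleR2 <- 1 - sseT / max(sstT, .Machine$double.eps)

  out <- list(conditionAveragedR2 = condR2, singleTrialR2 = singleR2,
              predicted = pm$pred, observed = pm$obs,
              keys = data.frame(length = pm$kl, phoneme = pm$kp))
  if (nBoot > 0L) {
    n <- nrow(points)
    draws <- replicate(nBoot, {
      ii <- sample.int(n, n, replace = TRUE)
      p2 <- predictMeans(points[ii, , drop = FALSE], lengths[ii], phonemes[ii])
      multivariateR2(p2$obs, p2$pred)
    })
    out$ci <- list(conditionAveragedR2 =
                     unname(quantile(draws, c(0.025, 0.975), na.rm = TRUE)))
  }
  if (nPerm > 0L) {
    null <- replicate(nPerm, {
      ii <- sample.int(nrow(points))
      p2 <- predictMeans(points, lengths[ii], phonemes[ii])
      multivariateR2(p2$obs, p2$pred)
    })
    out$permutation <- list(p = mean(null >= condR2), pFloor = 1 / nPerm,
                            null = null)
  }
  out
}

#' Marginal correlation matrix across length, position and phoneme
#'
#' Pairwise Pearson correlations between population activity vectors
#' averaged over trials sharing a sequence length and a phoneme identity at
#' one position, ordered length, then position, then phoneme. With
#' `subtractLengthMeans`, the per-length mean population vector is removed
#' from all trials first, isolating phoneme/position structure from shared
#' length offsets.
#'
#' @param points trials x features matrix
#' @param set a [ConditionSet-class]
#' @param labels integer condition index per trial
#' @param subtractLengthMeans remove per-length trial means first?
#' @return list with `correlation` matrix (`NA` where a group vector has
#'   zero variance), and `groups` data.frame (`length`, `position`,
#'   `phoneme`, `n`)
#' @export
marginalCorrelationMatrix <- function(points, set, labels,
                                      subtractLengthMeans = FALSE) {
  points <- as.matrix(points)
  lens <- set@lengthClass[labels]
  if (subtractLengthMeans) {
    for (L in unique(lens))
      points[lens == L, ] <- sweep(points[lens == L, , drop = FALSE], 2L,
                                   colMeans(points[lens == L, , drop = FALSE]))
  }
  groups <- list(); vecs <- list()
  for (L in sort(unique(lens))) {
    for (p in seq_len(L)) {
      cons <- slotConsonant(set, labels, p)
      for (q in inventory(set)) {
        rows <- which(lens == L & !is.na(cons) & cons == q)
        if (!length(rows)) next
        groups[[length(groups) + 1L]] <-
          data.frame(length = L, position = p, phoneme = q, n = length(rows))
        vecs[[length(vecs) + 1L]] <- colMeans(points[rows, , drop = FALSE])
      }
    }
  }
  V <- do.call(cbind, vecs)
  groups <- do.call(rbind, groups)
  sdv <- apply(V, 2L, sd)
  C <- suppressWarnings(cor(V))
  C[sdv == 0, ] <- NA; C[, sdv == 0] <- NA
  lbl <- paste0("L", groups$length, ".C", groups$position, ".", groups$phoneme)
  dimnames(C) <- list(lbl, lbl)
  list(correlation = C, groups = groups)
}
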