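## Synthetic instructed-delay sessions with a known linear compositional code.
##
## The generator realizes the generative structure the analyses presuppose:
## binned (20 ms) threshold-crossing counts and spike-band power on a
## microelectrode array, trials with cue-listening / preparatory-delay /
## attempted-speech epochs, full-factorial consonant-sequence cues, and a
## latent linear code with controllable cross-position alignment,
## position-dependent gain, a sequence-length axis, word-boundary truncation,
## and epoch-shared vs epoch-private structure.

#' Generator configuration
#'
#' @param nFeatures total feature count; two streams (threshold-crossing
#'   count, spike-band power) per electrode, so `nFeatures = 128` emulates a
#'   64-electrode array. Must be even.
#' @param snr signal-to-noise ratio at the population level: the total
#'   standard deviation of the noiseless preparatory-epoch condition means
#'   across the latent population vector (root sum over channels of the
#'   per-channel variance over conditions), divided by the per-bin,
#'   per-channel noise standard deviation (1 on the latent z-score scale).
#'   Individual channels therefore carry weak signal (order
#'   `snr / sqrt(nLatent)` per bin), as in real array recordings, and
#'   decoding power comes from pooling channels and time bins. `Inf` gives
#'   a noiseless session; `0` removes the condition-dependent signal.
#' @param noiseModel `"gaussian"` (additive on the latent z-score scale,
#'   the default since all analyses consume z-scored features) or
#'   `"poisson"` (rates clipped at zero, integer counts drawn per bin).
#' @param driftSd standard deviation of the per-block constant offset
#'   emulating slow session drift.
#' @param binMs bin width in milliseconds.
#' @param poissonBaseHz baseline event rate for the Poisson noise model.
#' @return a validated configuration list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(nFeatures = 128L, snr = 2, noiseModel = c("gaussian", "poisson"),
                            driftSd = 0, binMs = 20, poissonBaseHz = 50) {
  noiseModel <- match.arg(noiseModel)
  nFeatures <- as.integer(nFeatures)
  stopifnot(nFeatures >= 2L, nFeatures %% 2L == 0L, snr >= 0, binMs > 0, driftSd >= 0)
  structure(list(nFeatures = nFeatures, snr = snr, noiseModel = noiseModel,
                 driftSd = driftSd, binMs = binMs, poissonBaseHz = poissonBaseHz),
            class = "GeneratorConfig")
}

## unit-norm zero-sum simplex coordinates for M phonemes (M x M, rank M-1):
## mutually equidistant, pairwise cosine -1/(M-1)
simplexCoords <- function(M) {
  if (M == 1L) return(matrix(0, 1L, 1L))
  S <- diag(M) - 1 / M
  S / sqrt(1 - 1 / M)
}

#' Construct a ground-truth compositional sequence code
#'
#' Builds per-position phoneme coefficient vectors whose like-phoneme
#' cross-position cosines exactly match a requested alignment matrix, by a
#' shared-component plus orthogonal-residual construction: the alignment
#' Gram matrix is factored (eigen square root) and applied across banks of
#' mutually orthonormal latent directions, one bank per phoneme-simplex
#' dimension. Within each position the phoneme vectors are unit-norm,
#' mutually equidistant and sum to zero (the identifiability gauge matching
#' the one-hot + intercept encoding model). The sequence-length and
#' word-boundary axes are drawn orthogonal to every phoneme vector.
#'
#' @param set a [ConditionSet-class] declaring the consonant inventory and
#'   (via its longest condition) the number of slots.
#' @param config a [generatorConfig()] (supplies the latent dimensionality,
#'   `nFeatures / 2`).
#' @param alignment slots x slots matrix of target like-phoneme cosines
#'   (unit diagonal, entries in `[-1, 1]`, positive semidefinite), or a
#'   single number applied to every off-diagonal entry.
#' @param gains per-slot scalar gains (> 0); position-dependent scaling of
#'   the phoneme code.
#' @param lengthGain scalar gain of the sequence-length axis.
#' @param boundaryAxisGain scalar gain of the word-boundary indicator axis.
#' @param boundaryGain multiplier in `[0, 1]` applied during the preparatory
#'   epoch to phoneme vectors of slots after the first word boundary
#'   (0 = full truncation of the plan at the boundary).
#' @param epochGains named numeric `c(cue=, prep=, speech=)` scaling the
#'   shared code per epoch.
#' @param epochPrivateGain gain of epoch-private phoneme codes (orthogonal
#'   across epochs and to the shared code); 0 (default) makes cross-epoch
#'   generalization perfect, > 0 with zero `epochGains` makes it fail.
#' @param baselineSd standard deviation of the per-channel baseline offset.
#' @param seed optional integer seed for the random orthonormal basis.
#' @return a [GroundTruthCode-class].
#' @export
makeGroundTruthCode <- function(set, config = generatorConfig(),
                                alignment = 0.6, gains = NULL,
                                lengthGain = 1, boundaryAxisGain = 1,
                                boundaryGain = 1,
                                epochGains = c(cue = 1, prep = 1, speech = 1),
                                epochPrivateGain = 0,
                                baselineSd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inv <- inventory(set)
  M <- length(inv)
  P <- max(set@lengthClass)
  nLatent <- config$nFeatures %/% 2L
  if (is.null(gains)) gains <- rep(1, P)
  stopifnot(length(gains) == P, all(gains > 0))
  if (length(alignment) == 1L) {
    A <- matrix(alignment, P, P); diag(A) <- 1
  } else A <- alignment
  stopifnot(nrow(A) == P, ncol(A) == P, all(abs(A) <= 1), all(diag(A) == 1))
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("construction error: alignment matrix is not a valid Gram target ",
         "(not positive semidefinite)")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), P)

  nShared <- M * P + 2L
  nPrivate <- if (epochPrivateGain > 0) 3L * M * P else 0L
  if (nShared > nLatent)
    stop("construction error: nFeatures too small for inventory x slots")
  nOrtho <- min(nShared + nPrivate, nLatent)
  Q <- qr.Q(qr(matrix(rnorm(nLatent * nOrtho), nLatent, nOrtho)))

  S <- simplexCoords(M)                     # M phonemes x M simplex dims
  ## orthonormal bank: columns (d-1)*P + k  for simplex dim d, slot k
  b <- array(0, dim = c(P, M, nLatent))
  for (p in seq_len(P)) {
    for (j in seq_len(M)) {
      v <- numeric(nLatent)
      for (d in seq_len(M)) {
        if (S[j, d] == 0) next
        for (k in seq_len(P)) {
          if (L[p, k] == 0) next
          v <- v + S[j, d] * L[p, k] * Q[, (d - 1L) * P + k]
        }
      }
      b[p, j, ] <- v
    }
  }
  lengthAxis <- Q[, M * P + 1L]
  boundaryAxis <- Q[, M * P + 2L]

  epochPrivate <- list()
  if (epochPrivateGain > 0) {
    epochs <- c("cue", "prep", "speech")
    for (e in seq_along(epochs)) {
      be <- array(0, dim = c(P, M, nLatent))
      for (p in seq_len(P)) {
        for (j in seq_len(M)) {
          v <- numeric(nLatent)
          for (d in seq_len(M)) {
            col <- nShared + (e - 1L) * M * P + (d - 1L) * P + p
            if (col <= nOrtho) {
              v <- v + S[j, d] * Q[, col]
            } else {
              ## fall back to a random unit direction when the latent space
              ## cannot hold fully orthogonal private codes
              r <- rnorm(nLatent)
              v <- v + S[j, d] * r / sqrt(sum(r^2))
            }
          }
          be[p, j, ] <- v
        }
      }
      epochPrivate[[epochs[e]]] <- be
    }
  }

  new("GroundTruthCode",
      inventory = inv, nLatent = nLatent,
      baseline = rnorm(nLatent, 0, baselineSd),
      phonemeVectors = b, gains = as.numeric(gains), alignment = A,
      lengthAxis = lengthAxis, lengthGain = lengthGain,
      boundaryAxis = boundaryAxis, boundaryAxisGain = boundaryAxisGain,
      boundaryGain = boundaryGain,
      epochGains = epochGains, epochPrivate = epochPrivate,
      epochPrivateGain = epochPrivateGain, amplitude = 1)
}

#' Realized like-phoneme cosine between two positions of a code
#'
#' @param code a [GroundTruthCode-class]
#' @param p,q slot indices
#' @return mean cosine over like-phoneme vector pairs
#' @export
codeAlignment <- function(code, p, q) {
  M <- dim(code@phonemeVectors)[2]
  mean(vapply(seq_len(M), function(j) {
    a <- code@phonemeVectors[p, j, ]; b <- code@phonemeVectors[q, j, ]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1)))
}

#' Epoch timing specification for simulated trials
#'
#' All times in seconds. The instructed delay runs from audio-cue offset to
#' the go cue; `delayJitter` adds a uniform `[0, delayJitter]` random
#' extension per trial. Recording starts at cue onset (bin 0) and lasts
#' `cue + delay + delayJitter + react + post` seconds for every trial.
#'
#' @param cue audio-cue duration.
#' @param delay minimum instructed-delay duration.
#' @param delayJitter uniform jitter added to the delay.
#' @param react go-cue to speech-onset latency.
#' @param post recording retained after speech onset.
#' @return a list of class `"EpochSpec"`.
#' @export
epochSpec <- function(cue = 1.0, delay = 1.0, delayJitter = 0,
                      react = 0.3, post = 0.7) {
  stopifnot(cue > 0, delay > 0, delayJitter >= 0, react > 0, post > 0)
  structure(list(cue = cue, delay = delay, delayJitter = delayJitter,
                 react = react, post = post), class = "EpochSpec")
}

#' Build a balanced, shuffled trial plan
#'
#' @param set a [ConditionSet-class].
#' @param repeats trials per condition (>= 1).
#' @param spec an [epochSpec()].
#' @param nRest number of do-nothing control trials to append.
#' @param nBlocks number of recording blocks (trials split contiguously).
#' @param seed optional integer seed controlling shuffle order and jitter.
#' @return data.frame with one row per trial: `condition` (index into the
#'   set, `NA` for do-nothing), `block`, and event times `cue_onset`,
#'   `cue_offset`, `go_cue`, `speech_onset`.
#' @export
makeTrialPlan <- function(set, repeats, spec = epochSpec(), nRest = 0L,
                          nBlocks = 1L, seed = NULL) {
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1L) stop("repeats must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cond <- rep(seq_len(nConditions(set)), each = repeats)
  cond <- c(cond, rep(NA_integer_, nRest))
  cond <- cond[sample.int(length(cond))]
  n <- length(cond)
  jit <- if (spec$delayJitter > 0) runif(n, 0, spec$delayJitter) else numeric(n)
  data.frame(
    condition = cond,
    block = sort(rep(seq_len(nBlocks), length.out = n)),
    cue_onset = 0,
    cue_offset = spec$cue,
    go_cue = spec$cue + spec$delay + jit,
    speech_onset = spec$cue + spec$delay + jit + spec$react,
    duration = spec$cue + spec$delay + spec$delayJitter + spec$react + spec$post
  )
}

## per-epoch condition signal matrices (conditions x latent), amplitude 1
conditionSignals <- function(code, set) {
  if (is(code, "ConditionCode")) {
    if (nrow(code@epochSignals$prep) != nConditions(set))
      stop("label error: code conditions do not match the condition set")
    return(code@epochSignals)
  }
  nC <- nConditions(set)
  nL <- code@nLatent
  P <- dim(code@phonemeVectors)[1]
  lens <- set@lengthClass
  static <- matrix(0, nC, nL)     # length + boundary terms, epoch-independent
  for (i in seq_len(nC)) {
    static[i, ] <- code@lengthGain * lens[i] * code@lengthAxis +
      code@boundaryAxisGain * (length(set@segmentation[[i]]) > 0) * code@boundaryAxis
  }
  epochs <- c("cue", "prep", "speech")
  sig <- lapply(epochs, function(e) {
    m <- matrix(0, nC, nL)
    for (i in seq_len(nC)) {
      seg <- set@segmentation[[i]]
      firstBoundary <- if (length(seg)) seg[1] else Inf
      v <- numeric(nL)            # shared code, scaled by the epoch gain
      w <- numeric(nL)            # epoch-private code, independent of it
      for (p in seq_len(min(lens[i], P))) {
        j <- match(set@consonants[i, p], code@inventory)
        trunc <- if (e == "prep" && p > firstBoundary) code@boundaryGain else 1
        v <- v + code@gains[p] * trunc * code@phonemeVectors[p, j, ]
        if (code@epochPrivateGain > 0)
          w <- w + code@epochPrivateGain * code@gains[p] *
            code@epochPrivate[[e]][p, j, ]
      }
      m[i, ] <- code@epochGains[[e]] * v + w
    }
    m + static
  })
  names(sig) <- epochs
  sig
}

#' Simulate a session from a ground-truth code and trial plan
#'
#' Per trial and 20 ms bin, the latent mean is
#' `baseline + epochGain[epoch] * sum_p gain[p] * trunc * b[p][consonant]
#'  + lengthGain * lengthClass * lengthAxis + boundaryAxisGain * 1[two-word]
#'  * boundaryAxis + epoch-private code + block drift`,
#' where `trunc` is `boundaryGain` for slots after the first word boundary
#' during the preparatory epoch and 1 otherwise. Each latent channel is read
#' out as two feature streams (threshold-crossing count, spike-band power)
#' with independent noise. The condition-dependent part of the signal is
#' scaled so that the configured `snr` holds on the preparatory epoch (see
#' [generatorConfig()]).
#'
#' @param code a [GroundTruthCode-class].
#' @param plan a trial plan from [makeTrialPlan()].
#' @param set the [ConditionSet-class] the plan indexes.
#' @param config a [generatorConfig()].
#' @param seed optional integer seed for the noise draws.
#' @return a [SessionData-class].
#' @export
simulateSession <- function(code, plan, set, config = generatorConfig(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  known <- plan$condition[!is.na(plan$condition)]
  if (length(known) && (min(known) < 1L || max(known) > nConditions(set)))
    stop("label error: plan condition outside condition set")
  binW <- config$binMs / 1000
  nT <- nrow(plan)
  nBin <- ceiling(max(plan$duration) / binW - 1e-9)
  nL <- code@nLatent
  nF <- 2L * nL
  sig <- conditionSignals(code, set)

  ## snr calibration on preparatory-epoch condition means: total population
  ## signal sd (root sum of per-channel variances over conditions) relative
  ## to unit per-channel noise
  prep <- sig$prep
  sBar <- sqrt(sum(apply(prep, 2L, var)))
  ampl <- if (is.infinite(config$snr)) 1
          else if (sBar > 0) config$snr / sBar else 0
  noiseSd <- if (is.infinite(config$snr)) 0 else 1

  binStart <- (seq_len(nBin) - 1L) * binW
  blocks <- sort(unique(plan$block))
  drift <- matrix(rnorm(length(blocks) * nL, 0, config$driftSd),
                  length(blocks), nL, dimnames = list(blocks, NULL))

  latent <- array(0, dim = c(nT, nBin, nL))
  for (t in seq_len(nT)) {
    ci <- plan$condition[t]
    m <- matrix(rep(code@baseline, each = nBin), nBin, nL)
    m <- m + matrix(rep(drift[as.character(plan$block[t]), ], each = nBin), nBin, nL)
    if (!is.na(ci)) {
      epoch <- ifelse(binStart < plan$cue_offset[t], "cue",
                      ifelse(binStart < plan$go_cue[t], "prep", "speech"))
      for (e in c("cue", "prep", "speech")) {
        rows <- which(epoch == e)
        if (length(rows))
          m[rows, ] <- m[rows, ] + matrix(rep(ampl * sig[[e]][ci, ], each = length(rows)),
                                          length(rows), nL)
      }
    }
    latent[t, , ] <- m
  }

  feats <- array(0, dim = c(nT, nBin, nF))
  if (config$noiseModel == "gaussian") {
    for (s in 1:2) {
      idx <- ((s - 1L) * nL + 1L):(s * nL)
      feats[, , idx] <- latent +
        array(rnorm(nT * nBin * nL, 0, noiseSd), dim = dim(latent))
    }
  } else {
    r0 <- config$poissonBaseHz
    for (s in 1:2) {
      idx <- ((s - 1L) * nL + 1L):(s * nL)
      lam <- pmax(0, r0 * (1 + latent / max(config$snr, 1))) * binW
      feats[, , idx] <- array(rpois(length(lam), as.numeric(lam)),
                              dim = dim(latent))
    }
  }
  featureNames <- c(paste0("tx", seq_len(nL)), paste0("sbp", seq_len(nL)))
  new("SessionData",
      features = feats,
      labels = as.integer(plan$condition),
      conditionSet = set,
      events = plan[, c("cue_onset", "cue_offset", "go_cue", "speech_onset")],
      blockIds = as.integer(plan$block),
      binWidth = binW,
      featureNames = featureNames)
}

#' Noiseless condition means implied by a code (latent space)
#'
#' The exact per-epoch condition-mean matrices (conditions x latent channels)
#' at amplitude 1, i.e. the ground truth that analyses should recover.
#'
#' @param code a [GroundTruthCode-class]
#' @param set the matching [ConditionSet-class]
#' @return named list of matrices for epochs `cue`, `prep`, `speech`
#'   (baseline included)
#' @export
groundTruthMeans <- function(code, set) {
  sig <- conditionSignals(code, set)
  lapply(sig, function(m) sweep(m, 2L, code@baseline, "+"))
}

#' ConditionCode: arbitrary (non-compositional) per-condition means
#'
#' A degenerate-generator counterpart of [GroundTruthCode-class] that stores
#' explicit per-epoch condition-mean matrices instead of a factored code;
#' used to generate sessions whose condition means carry no compositional
#' structure at all.
#'
#' @slot epochSignals named list (cue, prep, speech) of conditions x latent
#'   mean matrices.
#' @slot baseline per-latent offset.
#' @slot nLatent latent dimensionality.
#' @export
setClass("ConditionCode",
  representation(epochSignals = "list", baseline = "numeric",
                 nLatent = "integer"))

#' Construct a strictly non-compositional condition code
#'
#' Draws an independent random mean vector per condition, then projects out
#' the entire additive position x phoneme (+ length + boundary + intercept)
#' subspace, leaving pure interaction structure: no linear compositional
#' model can capture any of the resulting condition-mean variance. The same
#' means are used in every epoch (scaled by `epochGains`), so epoch
#' generalization remains intact while compositionality is absent.
#'
#' @param set a [ConditionSet-class]
#' @param config a [generatorConfig()]
#' @param epochGains named numeric `c(cue=, prep=, speech=)`
#' @param seed optional integer seed
#' @return a [ConditionCode-class]
#' @export
makeNonCompositionalCode <- function(set, config = generatorConfig(),
                                     epochGains = c(cue = 1, prep = 1,
                                                    speech = 1),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nC <- nConditions(set)
  nLatent <- config$nFeatures %/% 2L
  R <- matrix(rnorm(nC * nLatent), nC, nLatent)
  ## additive subspace: one-hot slot x phoneme design + length class +
  ## boundary indicator + intercept, evaluated per condition
  D <- buildDesignMatrix(set, seq_len(nC))$X
  D <- cbind(D, set@lengthClass,
             vapply(set@segmentation, length, integer(1)) > 0L)
  Q <- qr.Q(qr(D))
  R <- R - Q %*% (t(Q) %*% R)
  new("ConditionCode",
      epochSignals = lapply(as.list(epochGains), function(g) g * R)[
        c("cue", "prep", "speech")],
      baseline = numeric(nLatent), nLatent = as.integer(nLatent))
}
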