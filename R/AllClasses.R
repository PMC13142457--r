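#' @import methods
#' @importFrom stats rnorm runif rpois sd var cor quantile kruskal.test
#'   pt plogis p.adjust aggregate setNames ks.test
#' @importFrom utils head write.csv read.csv
NULL

#' ConditionSet: a factorial set of consonant-sequence conditions
#'
#' A `ConditionSet` enumerates the cue conditions of an instructed-delay
#' sequence-production task: ordered consonant sequences embedded in a
#' fixed-vowel template (e.g. CVCVC), optionally carrying a phonological
#' word-boundary segmentation and a reserved do-nothing control.
#'
#' @slot inventory character vector of consonant tokens (ARPABET), in the
#'   order that defines lexicographic condition ordering.
#' @slot vowel single vowel token shared by all conditions.
#' @slot consonants character matrix, conditions x slots; `NA` pads unused
#'   slots for shorter sequences in mixed-length sets.
#' @slot lengthClass integer vector, number of consonant slots per condition.
#' @slot segmentation list of integer vectors; word-boundary indices (a
#'   boundary after consonant slot `b` is recorded as `b`); `integer(0)`
#'   means a single word.
#' @slot template character vector of sequence-shape tags (e.g. "CVCVC").
#' @slot includesRest logical; whether a do-nothing control is part of the
#'   task (never counted among factorial conditions).
#'
#' @seealso [buildFullFactorial()], [buildWordBoundarySet()],
#'   [singlePositionPairs()]
#' @export
setClass("ConditionSet",
  representation(
    inventory    = "character",
    vowel        = "character",
    consonants   = "matrix",
    lengthClass  = "integer",
    segmentation = "list",
    template     = "character",
    includesRest = "logical"
  )
)

setValidity("ConditionSet", function(object) {
  msg <- character(0)
  n <- nrow(object@consonants)
  if (length(object@inventory) < 1L) msg <- c(msg, "inventory must be non-empty")
  if (anyDuplicated(object@inventory)) msg <- c(msg, "inventory tokens must be unique")
  if (length(object@lengthClass) != n) msg <- c(msg, "lengthClass length mismatch")
  if (length(object@segmentation) != n) msg <- c(msg, "segmentation length mismatch")
  if (length(object@template) != n) msg <- c(msg, "template length mismatch")
  for (i in seq_len(n)) {
    L <- object@lengthClass[i]
    cons <- object@consonants[i, seq_len(L)]
    if (anyNA(cons)) { msg <- c(msg, "NA consonant inside declared length"); break }
    if (!all(cons %in% object@inventory)) { msg <- c(msg, "consonant outside inventory"); break }
    seg <- object@segmentation[[i]]
    if (length(seg)) {
      if (any(seg < 1L | seg >= L)) { msg <- c(msg, "segmentation index not interior"); break }
      if (is.unsorted(seg, strictly = TRUE)) { msg <- c(msg, "segmentation not strictly increasing"); break }
    }
  }
  if (anyDuplicated(conditionStrings(object))) msg <- c(msg, "conditions are not unique")
  if (length(msg)) msg else TRUE
})

#' GroundTruthCode: the generator's latent linear sequence code
#'
#' Holds the latent compositional code realized by [makeGroundTruthCode()]:
#' per-position phoneme coefficient vectors with controlled cross-position
#' cosine alignment, position gains, a sequence-length axis, a word-boundary
#' axis with a preparatory truncation gain, and per-epoch scalings of the
#' shared code plus optional epoch-private codes.
#'
#' Vectors live in the latent electrode space (`nLatent` dimensions); the
#' simulator reads each latent channel out as two noisy feature streams
#' (threshold-crossing counts and spike-band power).
#'
#' @slot inventory consonant tokens the code covers.
#' @slot nLatent latent dimensionality (electrodes).
#' @slot baseline per-latent offset.
#' @slot phonemeVectors array slots x phonemes x latent; unit-norm,
#'   zero-sum within each slot.
#' @slot gains per-slot scalar gains.
#' @slot alignment slot x slot matrix of target like-phoneme cosines.
#' @slot lengthAxis unit vector orthogonal to all phoneme vectors.
#' @slot lengthGain scalar multiplying `lengthAxis` x (centered length class).
#' @slot boundaryAxis unit vector orthogonal to all phoneme vectors.
#' @slot boundaryAxisGain scalar multiplying `boundaryAxis` for two-word cues.
#' @slot boundaryGain multiplier in [0,1] applied during the preparatory
#'   epoch to phoneme vectors of slots after the first word boundary.
#' @slot epochGains named numeric (cue, prep, speech) scaling the shared code.
#' @slot epochPrivate list (cue, prep, speech) of slot x phoneme x latent
#'   arrays of epoch-specific codes, or empty list if none.
#' @slot epochPrivateGain scalar gain of the epoch-private codes.
#' @slot amplitude scalar converting unit code vectors to signal units
#'   (set by the snr calibration in [makeGroundTruthCode()]).
#' @export
setClass("GroundTruthCode",
  representation(
    inventory        = "character",
    nLatent          = "integer",
    baseline         = "numeric",
    phonemeVectors   = "array",
    gains            = "numeric",
    alignment        = "matrix",
    lengthAxis       = "numeric",
    lengthGain       = "numeric",
    boundaryAxis     = "numeric",
    boundaryAxisGain = "numeric",
    boundaryGain     = "numeric",
    epochGains       = "numeric",
    epochPrivate     = "list",
    epochPrivateGain = "numeric",
    amplitude        = "numeric"
  )
)

setValidity("GroundTruthCode", function(object) {
  msg <- character(0)
  d <- dim(object@phonemeVectors)
  if (length(d) != 3L) return("phonemeVectors must be slots x phonemes x latent")
  if (d[2] != length(object@inventory)) msg <- c(msg, "phoneme dim mismatch with inventory")
  if (d[3] != object@nLatent) msg <- c(msg, "latent dim mismatch")
  if (length(object@gains) != d[1]) msg <- c(msg, "gains length mismatch")
  if (object@boundaryGain < 0 || object@boundaryGain > 1)
    msg <- c(msg, "boundaryGain must lie in [0,1]")
  ## identifiability: zero-sum within each slot
  for (p in seq_len(d[1])) {
    s <- colSums(matrix(object@phonemeVectors[p, , ], nrow = d[2]))
    if (max(abs(s)) > 1e-8) { msg <- c(msg, "phoneme vectors not zero-sum within slot"); break }
  }
  if (!all(c("cue", "prep", "speech") %in% names(object@epochGains)))
    msg <- c(msg, "epochGains must be named cue/prep/speech")
  if (length(msg)) msg else TRUE
})

#' SessionData: binned neural features with trial labels and events
#'
#' The central data container: a trials x time-bins x features tensor of
#' binned neural activity (threshold-crossing counts and spike-band power
#' streams), per-trial condition labels resolving into a [ConditionSet-class],
#' per-trial epoch event times, and block identifiers.
#'
#' @slot features numeric array, trials x bins x features.
#' @slot labels integer vector of condition indices into `conditionSet`
#'   (`NA` marks do-nothing control trials).
#' @slot conditionSet the [ConditionSet-class] the labels refer to.
#' @slot events data.frame with columns `cue_onset`, `cue_offset`, `go_cue`,
#'   `speech_onset` (seconds on the trial clock; bin 0 starts at time 0).
#' @slot blockIds integer block index per trial (slow-drift grouping).
#' @slot binWidth bin width in seconds (0.02 for 20 ms bins).
#' @slot featureNames character vector naming the feature columns.
#' @export
setClass("SessionData",
  representation(
    features     = "array",
    labels       = "integer",
    conditionSet = "ConditionSet",
    events       = "data.frame",
    blockIds     = "integer",
    binWidth     = "numeric",
    featureNames = "character"
  )
)

setValidity("SessionData", function(object) {
  msg <- character(0)
  d <- dim(object@features)
  if (length(d) != 3L) return("features must be trials x bins x features")
  if (length(object@labels) != d[1]) msg <- c(msg, "labels length mismatch")
  if (nrow(object@events) != d[1]) msg <- c(msg, "events rows mismatch")
  need <- c("cue_onset", "cue_offset", "go_cue", "speech_onset")
  if (!all(need %in% names(object@events)))
    return(paste("events must contain:", paste(need, collapse = ", ")))
  if (length(object@blockIds) != d[1]) msg <- c(msg, "blockIds length mismatch")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  ev <- as.matrix(object@events[, need])
  ok <- apply(ev, 1L, function(r) all(is.na(r)) || !is.unsorted(r[!is.na(r)], strictly = TRUE))
  if (!all(ok)) msg <- c(msg, "event times must be strictly increasing per trial")
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > nConditions(object@conditionSet)))
    msg <- c(msg, "labels outside condition set")
  if (length(object@featureNames) && length(object@featureNames) != d[3])
    msg <- c(msg, "featureNames length mismatch")
  if (length(msg)) msg else TRUE
})

#' LDAModel: diagonal-regularized linear discriminant model
#'
#' Fisher discriminant model in which the pooled within-class scatter is
#' replaced by its diagonal (features treated as conditionally independent
#' given the class). Produced by [fitDiagLDA()].
#'
#' @slot classes ordered class labels (K).
#' @slot globalMean per-feature global mean.
#' @slot classMeans K x features matrix of class means.
#' @slot classCounts per-class sample counts.
#' @slot totalCount total samples N.
#' @slot diagWithin per-feature pooled within-class scatter diagonal, with
#'   variance floor applied.
#' @slot projection features x components discriminant matrix V (at most
#'   K - 1 columns, descending eigenvalue order, sign-fixed).
#' @slot eigenvalues eigenvalues of D^-1 B for the retained components.
#' @export
setClass("LDAModel",
  representation(
    classes     = "character",
    globalMean  = "numeric",
    classMeans  = "matrix",
    classCounts = "integer",
    totalCount  = "integer",
    diagWithin  = "numeric",
    projection  = "matrix",
    eigenvalues = "numeric"
  )
)

setValidity("LDAModel", function(object) {
  msg <- character(0)
  K <- length(object@classes)
  if (nrow(object@classMeans) != K) msg <- c(msg, "classMeans rows != K")
  if (ncol(object@projection) > max(K - 1L, 0L)) msg <- c(msg, "more than K-1 components")
  if (any(object@diagWithin <= 0)) msg <- c(msg, "diagWithin must be positive after flooring")
  if (length(msg)) msg else TRUE
})

#' EncodingModel: position-specific linear phoneme encoding model
#'
#' Ridge-regression model of per-feature activity as an intercept plus a sum
#' of position-specific phoneme-identity coefficients,
#' y = b0 + p1' b1 + p2' b2 + p3' b3 + e, fit by [fitEncodingModel()].
#'
#' @slot intercept per-feature intercept.
#' @slot coef features x predictors coefficient matrix.
#' @slot columns data.frame describing predictor columns (`slot`, `phoneme`).
#' @slot alpha ridge penalty applied to the summed squared coefficients
#'   (intercept unpenalized).
#' @slot residScale per-feature residual standard deviation (training data).
#' @slot featureMask logical mask of the features the model was fit on,
#'   relative to the supplied response matrix.
#' @export
setClass("EncodingModel",
  representation(
    intercept   = "numeric",
    coef        = "matrix",
    columns     = "data.frame",
    alpha       = "numeric",
    residScale  = "numeric",
    featureMask = "logical"
  )
)

setValidity("EncodingModel", function(object) {
  if (ncol(object@coef) != nrow(object@columns))
    return("coef columns must match column descriptor rows")
  if (object@alpha < 0) return("alpha must be non-negative")
  TRUE
})
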