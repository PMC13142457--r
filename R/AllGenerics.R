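#' @rdname ConditionSet-class
#' @param object,x a `ConditionSet` or `SessionData`
#' @export
setGeneric("nConditions", function(object) standardGeneric("nConditions"))

#' @rdname ConditionSet-class
#' @export
setGeneric("conditionStrings", function(object) standardGeneric("conditionStrings"))

#' @rdname ConditionSet-class
#' @export
setGeneric("inventory", function(object) standardGeneric("inventory"))

#' @rdname SessionData-class
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname SessionData-class
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))

#' @rdname SessionData-class
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname SessionData-class
#' @export
setGeneric("featureTensor", function(object) standardGeneric("featureTensor"))

#' @rdname SessionData-class
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))

#' @rdname SessionData-class
#' @export
setGeneric("trialEvents", function(object) standardGeneric("trialEvents"))

#' @rdname SessionData-class
#' @export
setGeneric("conditionSet", function(object) standardGeneric("conditionSet"))

#' @rdname SessionData-class
#' @export
setGeneric("blockIds", function(object) standardGeneric("blockIds"))

setGeneric("binWidth", function(object) standardGeneric("binWidth"))

## ---- ConditionSet methods -------------------------------------------------

#' @rdname ConditionSet-class
setMethod("nConditions", "ConditionSet", function(object) nrow(object@consonants))

#' @describeIn ConditionSet-class canonical printable condition strings, e.g.
#'   `"KahNahSH"`, with a `|` marking a phonological word boundary.
setMethod("conditionStrings", "ConditionSet", function(object) {
  vapply(seq_len(nConditions(object)), function(i) {
    L <- object@lengthClass[i]
    cons <- object@consonants[i, seq_len(L)]
    tmpl <- strsplit(object@template[i], "")[[1]]
    out <- character(0)
    ci <- 0L
    for (ch in tmpl) {
      if (ch == "C") {
        ci <- ci + 1L
        out <- c(out, cons[ci])
        if (ci %in% object@segmentation[[i]]) out <- c(out, "|")
      } else {
        out <- c(out, tolower(object@vowel))
      }
    }
    paste(out, collapse = "")
  }, character(1))
})

#' @rdname ConditionSet-class
setMethod("inventory", "ConditionSet", function(object) object@inventory)

setMethod("show", "ConditionSet", function(object) {
  cat("ConditionSet with", nConditions(object), "conditions\n")
  cat("  inventory:", paste(object@inventory, collapse = ", "),
      " vowel:", object@vowel, "\n")
  cat("  templates:", paste(unique(object@template), collapse = ", "), "\n")
  nseg <- sum(vapply(object@segmentation, length, integer(1)) > 0L)
  if (nseg) cat("  two-word conditions:", nseg, "\n")
  if (object@includesRest) cat("  includes do-nothing control\n")
  cs <- conditionStrings(object)
  cat("  first conditions:", paste(head(cs, 5L), collapse = ", "),
      if (length(cs) > 5L) "..." else "", "\n")
})

## ---- SessionData methods --------------------------------------------------

#' @rdname SessionData-class
setMethod("nTrials", "SessionData", function(object) dim(object@features)[1])

#' @rdname SessionData-class
setMethod("nBins", "SessionData", function(object) dim(object@features)[2])

#' @rdname SessionData-class
setMethod("nFeatures", "SessionData", function(object) dim(object@features)[3])

#' @rdname SessionData-class
setMethod("featureTensor", "SessionData", function(object) object@features)

#' @rdname SessionData-class
setMethod("trialLabels", "SessionData", function(object) object@labels)

#' @rdname SessionData-class
setMethod("trialEvents", "SessionData", function(object) object@events)

#' @rdname SessionData-class
setMethod("conditionSet", "SessionData", function(object) object@conditionSet)

#' @rdname SessionData-class
setMethod("blockIds", "SessionData", function(object) object@blockIds)

setMethod("binWidth", "SessionData", function(object) object@binWidth)

setMethod("show", "SessionData", function(object) {
  d <- dim(object@features)
  cat("SessionData:", d[1], "trials x", d[2], "bins x", d[3], "features\n")
  cat("  bin width:", object@binWidth * 1000, "ms;",
      length(unique(object@blockIds)), "block(s)\n")
  cat("  condition set:", nConditions(object@conditionSet), "conditions;",
      sum(is.na(object@labels)), "do-nothing trial(s)\n")
})

#' Subset a session by trials
#'
#' @param x a [SessionData-class]
#' @param i integer or logical trial index
#' @param j,...,drop ignored
#' @return a [SessionData-class] containing the selected trials
#' @export
setMethod("[", "SessionData", function(x, i, j, ..., drop = FALSE) {
  new("SessionData",
      features = x@features[i, , , drop = FALSE],
      labels = x@labels[i],
      conditionSet = x@conditionSet,
      events = x@events[i, , drop = FALSE],
      blockIds = x@blockIds[i],
      binWidth = x@binWidth,
      featureNames = x@featureNames)
})

setMethod("show", "LDAModel", function(object) {
  cat("Diagonal-regularized LDA model\n")
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
  cat("  features:", length(object@globalMean),
      " components:", ncol(object@projection), "\n")
  cat("  eigenvalues:", paste(signif(object@eigenvalues, 3), collapse = ", "), "\n")
})

setMethod("show", "EncodingModel", function(object) {
  cat("Linear phoneme-sequence encoding model (ridge alpha =", object@alpha, ")\n")
  cat("  features:", nrow(object@coef), " predictors:", ncol(object@coef), "\n")
  cat("  slots:", paste(unique(object@columns$slot), collapse = ", "), "\n")
})

setMethod("show", "GroundTruthCode", function(object) {
  d <- dim(object@phonemeVectors)
  cat("GroundTruthCode:", d[1], "slots x", d[2], "phonemes in",
      object@nLatent, "latent channels\n")
  cat("  gains:", paste(signif(object@gains, 3), collapse = ", "),
      " boundaryGain:", object@boundaryGain, "\n")
  cat("  epoch gains:", paste(names(object@epochGains),
      signif(object@epochGains, 3), sep = "=", collapse = ", "), "\n")
})
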