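## Factorial condition-set construction for instructed-delay sequence tasks.
## Conditions are ordered consonant sequences in a fixed-vowel template;
## "position" is the 1-based consonant slot index (C1 V C2 V C3 ...).

templateForSlots <- function(nSlots, shape = c("CVC", "CV", "VC")) {
  shape <- match.arg(shape)
  if (shape == "CVC") {
    ## alternating, consonant-initial and consonant-final: C(VC)^(n-1)
    paste(c("C", rep(c("V", "C"), nSlots - 1L)), collapse = "")
  } else if (shape == "CV") {
    paste(rep(c("C", "V"), nSlots), collapse = "")
  } else {
    paste(rep(c("V", "C"), nSlots), collapse = "")
  }
}

newConditionSet <- function(inventory, vowel, consonants, segmentation = NULL,
                            template = NULL, includesRest = FALSE) {
  consonants <- as.matrix(consonants)
  n <- nrow(consonants)
  lengthClass <- as.integer(rowSums(!is.na(consonants)))
  if (is.null(segmentation)) segmentation <- rep(list(integer(0)), n)
  if (is.null(template))
    template <- vapply(lengthClass, templateForSlots, character(1))
  new("ConditionSet",
      inventory = inventory, vowel = vowel,
      consonants = consonants, lengthClass = lengthClass,
      segmentation = segmentation, template = template,
      includesRest = includesRest)
}

#' Build a full-factorial consonant-sequence condition set
#'
#' Enumerates all `length(inventory)^nSlots` ordered consonant sequences for
#' a fixed-vowel template, in deterministic lexicographic order (inventory
#' order within each slot, earlier slots varying slowest), so that condition
#' indices are reproducible across runs.
#'
#' @param inventory character vector of consonant tokens (ARPABET), e.g.
#'   `c("K", "N", "SH", "T")`.
#' @param nSlots number of consonant slots (>= 1).
#' @param vowel fixed vowel token.
#' @param shape template family: `"CVC"` (consonant-initial and -final,
#'   e.g. CVCVC for 3 slots), `"CV"` or `"VC"`.
#' @param includesRest whether a do-nothing control accompanies the set
#'   (never counted among the factorial conditions).
#' @return a [ConditionSet-class] with `length(inventory)^nSlots` conditions.
#' @examples
#' cs <- buildFullFactorial(c("K", "N", "SH", "T"), 3)
#' nConditions(cs)  # 64
#' @export
buildFullFactorial <- function(inventory, nSlots, vowel = "AH",
                               shape = "CVC", includesRest = FALSE) {
  if (length(inventory) < 1L || anyDuplicated(inventory))
    stop("invalid design: inventory must be non-empty and unique")
  nSlots <- as.integer(nSlots)
  if (is.na(nSlots) || nSlots < 1L)
    stop("invalid design: nSlots must be >= 1")
  grids <- rev(expand.grid(rev(replicate(nSlots, inventory, simplify = FALSE)),
                           stringsAsFactors = FALSE))
  cons <- as.matrix(grids)
  dimnames(cons) <- list(NULL, paste0("C", seq_len(nSlots)))
  newConditionSet(inventory, vowel, cons,
                  template = rep(templateForSlots(nSlots, shape), nrow(cons)),
                  includesRest = includesRest)
}

#' Combine condition sets of different sequence lengths
#'
#' Stacks full-factorial sets built on the same inventory but different
#' numbers of slots (e.g. CV, CVC, CVCVC) into one mixed-length set, used
#' for sequence-length decoding and length-compositionality analyses.
#'
#' @param ... [ConditionSet-class] objects sharing an inventory and vowel.
#' @return a [ConditionSet-class] whose `lengthClass` distinguishes sources.
#' @export
combineConditionSets <- function(...) {
  sets <- list(...)
  inv <- sets[[1]]@inventory
  for (s in sets) {
    if (!identical(s@inventory, inv) || !identical(s@vowel, sets[[1]]@vowel))
      stop("invalid design: condition sets must share inventory and vowel")
  }
  maxSlots <- max(vapply(sets, function(s) ncol(s@consonants), integer(1)))
  cons <- do.call(rbind, lapply(sets, function(s) {
    m <- s@consonants
    if (ncol(m) < maxSlots)
      m <- cbind(m, matrix(NA_character_, nrow(m), maxSlots - ncol(m)))
    m
  }))
  dimnames(cons) <- list(NULL, paste0("C", seq_len(maxSlots)))
  newConditionSet(inv, sets[[1]]@vowel, cons,
                  segmentation = do.call(c, lapply(sets, function(s) s@segmentation)),
                  template = do.call(c, lapply(sets, function(s) s@template)),
                  includesRest = any(vapply(sets, function(s) s@includesRest, logical(1))))
}

#' Build a matched one-word / two-word condition set
#'
#' Enumerates all `length(inventory)^nSlots` consonant sequences and presents
#' each twice: once as a single word (empty segmentation) and once with a
#' phonological word boundary after consonant slot `boundarySlot`. Phonemic
#' content is identical within each pair; only the segmentation differs.
#'
#' @inheritParams buildFullFactorial
#' @param boundarySlot interior slot index after which the boundary falls
#'   (must satisfy `1 <= boundarySlot < nSlots`).
#' @return a [ConditionSet-class] with `2 * length(inventory)^nSlots`
#'   conditions; one-word versions come first, then their two-word partners
#'   in the same sequence order.
#' @examples
#' ws <- buildWordBoundarySet(c("K", "N", "SH"), 4, boundarySlot = 2)
#' nConditions(ws)  # 162
#' @export
buildWordBoundarySet <- function(inventory, nSlots, boundarySlot,
                                 vowel = "AH", shape = "CV",
                                 includesRest = FALSE) {
  nSlots <- as.integer(nSlots)
  boundarySlot <- as.integer(boundarySlot)
  if (is.na(nSlots) || nSlots < 2L)
    stop("invalid design: nSlots must be >= 2")
  if (is.na(boundarySlot) || boundarySlot < 1L || boundarySlot >= nSlots)
    stop("invalid design: boundary must be interior (1 <= b < nSlots)")
  base <- buildFullFactorial(inventory, nSlots, vowel = vowel, shape = shape)
  n <- nConditions(base)
  cons <- rbind(base@consonants, base@consonants)
  seg <- c(rep(list(integer(0)), n), rep(list(boundarySlot), n))
  newConditionSet(inventory, vowel, cons, segmentation = seg,
                  template = rep(base@template, 2L),
                  includesRest = includesRest)
}

#' Single-position difference pairs of conditions
#'
#' Returns every unordered pair of conditions that differ in exactly one
#' given consonant slot while agreeing in all other slots, in template, and
#' in segmentation — the condition pairs consumed by all pairwise decoding
#' analyses.
#'
#' @param set a [ConditionSet-class].
#' @param position 1-based consonant slot index at which the pair differs.
#' @return integer matrix with columns `a`, `b` of condition indices, in
#'   deterministic order (context-major, then inventory order).
#' @examples
#' cs <- buildFullFactorial(c("K", "N", "SH"), 3)
#' nrow(singlePositionPairs(cs, 2))  # 27
#' @export
singlePositionPairs <- function(set, position) {
  position <- as.integer(position)
  maxSlots <- max(set@lengthClass)
  if (is.na(position) || position < 1L || position > maxSlots)
    stop("index error: position out of range")
  keep <- which(set@lengthClass >= position)
  ## context key: everything except the consonant at `position`
  key <- vapply(keep, function(i) {
    cons <- set@consonants[i, seq_len(set@lengthClass[i])]
    cons[position] <- "_"
    paste(set@template[i], paste(cons, collapse = "."),
          paste(set@segmentation[[i]], collapse = ","), sep = "|")
  }, character(1))
  out <- list()
  for (k in unique(key)) {
    idx <- keep[key == k]
    if (length(idx) < 2L) next
    ## inventory order within the context
    ord <- order(match(set@consonants[cbind(idx, position)], set@inventory))
    idx <- idx[ord]
    cmb <- utils::combn(idx, 2L)
    out[[length(out) + 1L]] <- t(cmb)
  }
  if (!length(out))
    stop("design error: no qualifying pairs at this position")
  pairs <- do.call(rbind, out)
  colnames(pairs) <- c("a", "b")
  pairs
}

#' Pairs differing only in late positions (word-boundary analysis)
#'
#' Enumerates unordered pairs of conditions within the same segmentation
#' context that share consonants at `sharedSlots` exactly and differ in at
#' least one of the remaining slots.
#'
#' @param set a [ConditionSet-class] (typically from
#'   [buildWordBoundarySet()]).
#' @param sharedSlots slots that must match (default `1:2`).
#' @param segmented logical: pairs from the two-word (`TRUE`) or one-word
#'   (`FALSE`) context.
#' @return integer matrix with columns `a`, `b`.
#' @export
latePositionPairs <- function(set, sharedSlots = 1:2, segmented = FALSE) {
  isTwo <- vapply(set@segmentation, length, integer(1)) > 0L
  idx <- which(isTwo == segmented)
  if (!length(idx)) stop("design error: no conditions in requested context")
  key <- apply(set@consonants[idx, sharedSlots, drop = FALSE], 1L, paste, collapse = ".")
  out <- list()
  for (k in unique(key)) {
    grp <- idx[key == k]
    if (length(grp) < 2L) next
    cmb <- utils::combn(grp, 2L)
    out[[length(out) + 1L]] <- t(cmb)
  }
  pairs <- do.call(rbind, out)
  colnames(pairs) <- c("a", "b")
  pairs
}

#' Serialize a condition set to JSON
#'
#' Writes the inventory, vowel, templates and the ordered condition list
#' (consonants per slot plus word-boundary segmentation) as a human-readable
#' JSON document consumed by downstream tooling.
#'
#' @param set a [ConditionSet-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeConditionSet <- function(set, path) {
  doc <- list(
    schema = "phonoplan-conditions-1",
    inventory = set@inventory,
    vowel = set@vowel,
    includes_rest = set@includesRest,
    conditions = lapply(seq_len(nConditions(set)), function(i) {
      L <- set@lengthClass[i]
      list(consonants = as.list(set@consonants[i, seq_len(L)]),
           template = set@template[i],
           segmentation = as.list(set@segmentation[[i]]))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a condition set from JSON
#'
#' @param path path written by [writeConditionSet()]
#' @return a [ConditionSet-class]
#' @export
readConditionSet <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "phonoplan-conditions-1"))
    stop("version mismatch: expected schema phonoplan-conditions-1, found ",
         if (is.null(doc$schema)) "<none>" else doc$schema)
  lens <- vapply(doc$conditions, function(cc) length(cc$consonants), integer(1))
  maxSlots <- max(lens)
  cons <- t(vapply(doc$conditions, function(cc) {
    v <- unlist(cc$consonants)
    c(v, rep(NA_character_, maxSlots - length(v)))
  }, character(maxSlots)))
  if (maxSlots == 1L) cons <- matrix(cons, ncol = 1L)
  dimnames(cons) <- list(NULL, paste0("C", seq_len(maxSlots)))
  newConditionSet(unlist(doc$inventory), doc$vowel, cons,
                  segmentation = lapply(doc$conditions, function(cc)
                    as.integer(unlist(cc$segmentation))),
                  template = vapply(doc$conditions, function(cc)
                    cc$template, character(1)),
                  includesRest = isTRUE(doc$includes_rest))
}

## consonant at a slot, NA-safe for mixed-length sets and NA (rest) labels
slotConsonant <- function(set, idx, position) {
  out <- rep(NA_character_, length(idx))
  ok <- which(!is.na(idx) & position <= ncol(set@consonants))
  if (length(ok)) {
    val <- set@consonants[idx[ok], position]
    val[set@lengthClass[idx[ok]] < position] <- NA_character_
    out[ok] <- val
  }
  out
}
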