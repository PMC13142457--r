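## On-disk session bundle: a directory holding
##   metadata.json   - schema version, tensor shape, bin width, feature
##                     names, provenance (e.g. generator seed)
##   conditions.json - the condition set (writeConditionSet format)
##   trials.csv      - per-trial label index, block id and event times
##   features.bin    - dense float64 tensor, trials x bins x features in
##                     column-major (R array) order, little-endian
## A deliberately simple bespoke layout (documented here) rather than a
## neurophysiology container standard; converters are straightforward.

SESSION_SCHEMA <- "phonoplan-session-1"

#' Write a session bundle to disk
#'
#' @param session a [SessionData-class]
#' @param path directory to create/overwrite
#' @param provenance optional named list recorded verbatim in the metadata
#'   (e.g. `list(seed = 42)`)
#' @return `path`, invisibly
#' @export
writeSession <- function(session, path, provenance = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(session@features)
  meta <- list(schema = SESSION_SCHEMA,
               shape = as.list(d),
               bin_width_s = session@binWidth,
               feature_names = session@featureNames,
               byte_order = "little",
               provenance = provenance)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeConditionSet(session@conditionSet, file.path(path, "conditions.json"))
  tr <- cbind(data.frame(condition = session@labels,
                         block = session@blockIds),
              session@events)
  write.csv(tr, file.path(path, "trials.csv"), row.names = FALSE)
  con <- file(file.path(path, "features.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(session@features), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Validates the schema version, the tensor size against the recorded
#' shape, and the session invariants on load.
#'
#' @param path bundle directory written by [writeSession()]
#' @return a [SessionData-class]
#' @export
readSession <- function(path) {
  metaPath <- file.path(path, "metadata.json")
  if (!file.exists(metaPath)) stop("I/O error: no metadata.json under ", path)
  meta <- jsonlite::read_json(metaPath)
  if (!identical(meta$schema, SESSION_SCHEMA))
    stop("version mismatch: bundle schema is ",
         if (is.null(meta$schema)) "<none>" else meta$schema,
         ", reader expects ", SESSION_SCHEMA)
  d <- as.integer(unlist(meta$shape))
  binPath <- file.path(path, "features.bin")
  expected <- prod(d) * 8
  actual <- file.info(binPath)$size
  if (is.na(actual) || actual != expected)
    stop("corrupt bundle: features.bin holds ", actual,
         " bytes, metadata implies ", expected)
  con <- file(binPath, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(d), size = 8L, endian = "little")
  tr <- read.csv(file.path(path, "trials.csv"))
  need <- c("condition", "block", "cue_onset", "cue_offset", "go_cue",
            "speech_onset")
  if (!all(need %in% names(tr)))
    stop("validation error: trials.csv missing column(s): ",
         paste(setdiff(need, names(tr)), collapse = ", "))
  set <- readConditionSet(file.path(path, "conditions.json"))
  new("SessionData",
      features = array(x, dim = d),
      labels = as.integer(tr$condition),
      conditionSet = set,
      events = tr[, c("cue_onset", "cue_offset", "go_cue", "speech_onset")],
      blockIds = as.integer(tr$block),
      binWidth = as.numeric(meta$bin_width_s),
      featureNames = as.character(unlist(meta$feature_names)))
}
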