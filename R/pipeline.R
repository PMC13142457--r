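## Config-driven scenario runner: reproduces each figure-level analysis
## end-to-end (generate or load -> preprocess -> analyze -> stats), writing
## machine-readable results plus a log of every seed and window used.

scenarioNames <- c("fig1_pairwise", "fig2_geometry_encoding", "fig3_length",
                   "fig4_generalization", "fig5_words_boundary",
                   "recovery_suite")

defaultSessionConfig <- function(scenario) {
  base <- list(inventory = c("K", "N", "SH"), repeats = 10L, snr = 2,
               nFeatures = 128L, alignment = 0.6, driftSd = 0,
               epochPrivateGain = 0, boundaryGain = 1)
  if (scenario == "fig5_words_boundary")
    base$repeats <- 5L
  base
}

## build the session a scenario calls for (or load one from disk)
scenarioSession <- function(scenario, cfg, seed) {
  if (!is.null(cfg$sessionPath)) {
    ses <- readSession(cfg$sessionPath)
    return(list(session = zscoreSession(ses, blockSubtract = TRUE),
                set = conditionSet(ses), code = NULL))
  }
  sc <- utils::modifyList(defaultSessionConfig(scenario),
                          cfg$generator %||% list())
  gcfg <- generatorConfig(nFeatures = sc$nFeatures, snr = sc$snr,
                          driftSd = sc$driftSd)
  set <- switch(scenario,
    fig3_length = combineConditionSets(
      buildFullFactorial(sc$inventory, 1L, shape = "CV"),
      buildFullFactorial(sc$inventory, 2L, shape = "CV"),
      buildFullFactorial(sc$inventory, 3L, shape = "CVC")),
    fig5_words_boundary = buildWordBoundarySet(sc$inventory, 4L,
                                               boundarySlot = 2L, shape = "CV"),
    buildFullFactorial(sc$inventory, 3L, shape = "CVC"))
  code <- makeGroundTruthCode(set, gcfg, alignment = sc$alignment,
                              boundaryGain = sc$boundaryGain,
                              epochPrivateGain = sc$epochPrivateGain,
                              seed = seed)
  plan <- makeTrialPlan(set, sc$repeats, seed = seed + 1L)
  ses <- simulateSession(code, plan, set, gcfg, seed = seed + 2L)
  list(session = zscoreSession(ses), set = set, code = code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a figure-level analysis scenario end-to-end
#'
#' Generates (or loads) a session, preprocesses it, and runs the scenario's
#' analysis chain, returning a results bundle and optionally writing a JSON
#' summary, CSV tables and a parameter log to `outDir`.
#'
#' Scenarios: `fig1_pairwise` (per-position pairwise decoding),
#' `fig2_geometry_encoding` (cross-position generalization, displacement
#' geometry, encoding model + cosine summary), `fig3_length` (length
#' decoding and compositional prediction), `fig4_generalization`
#' (cross-epoch generalization), `fig5_words_boundary` (boundary decoding
#' and late-position truncation), `recovery_suite` (alignment parameter
#' recovery over a cosine grid).
#'
#' @param config list with `scenario`, `seed`, optional `generator`
#'   overrides (inventory, repeats, snr, nFeatures, alignment, driftSd,
#'   epochPrivateGain, boundaryGain), optional `sessionPath` to load a
#'   bundle instead of generating, optional analysis overrides (`nBoot`,
#'   `nPerm`, `maxPairs`), and optional `shuffleLabels` (leakage sentinel).
#' @param outDir optional output directory for `summary.json`, CSV tables
#'   and `log.json`
#' @return a results list (class `"ScenarioResult"`) with `scenario`,
#'   `seed`, `summary` (flat named numerics), `detail`, and `log`
#' @export
runScenario <- function(config, outDir = NULL) {
  scenario <- config$scenario
  if (is.null(scenario) || !scenario %in% scenarioNames)
    stop("config error: unknown scenario '", scenario %||% "<missing>",
         "'; valid: ", paste(scenarioNames, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  nBoot <- config$nBoot %||% 0L
  nPerm <- config$nPerm %||% 0L
  maxPairs <- config$maxPairs %||% Inf
  set.seed(seed)

  if (scenario == "recovery_suite") {
    grid <- config$alignmentGrid %||% c(0, 0.3, 0.6, 0.9)
    rows <- lapply(seq_along(grid), function(i) {
      cc <- utils::modifyList(config, list(scenario = "fig2_geometry_encoding",
                                           seed = seed + 100L * i))
      cc$generator <- utils::modifyList(cc$generator %||% list(),
                                        list(alignment = grid[i]))
      r <- runScenario(cc)
      data.frame(alignment = grid[i],
                 recoveredCosine23 = r$summary[["cosine_2_3"]],
                 normalizedGeneralization23 = r$summary[["normgen_2_3"]])
    })
    tab <- do.call(rbind, rows)
    res <- list(scenario = scenario, seed = seed,
                summary = c(recovery_max_abs_error =
                              max(abs(tab$recoveredCosine23 - tab$alignment))),
                detail = list(recovery = tab),
                log = list(scenario = scenario, seed = seed, grid = grid))
    class(res) <- "ScenarioResult"
    if (!is.null(outDir)) writeScenarioFiles(res, outDir)
    return(res)
  }

  ss <- scenarioSession(scenario, config, seed)
  session <- ss$session
  if (isTRUE(config$shuffleLabels)) session <- permuteLabels(session)
  set <- conditionSet(session)
  log <- list(scenario = scenario, seed = seed,
              shuffleLabels = isTRUE(config$shuffleLabels),
              nTrials = nTrials(session), nFeatures = nFeatures(session))
  summary <- c(); detail <- list()

  if (scenario == "fig1_pairwise") {
    win <- epochWindow("go_cue", -0.8, 0)
    log$window <- "go_cue [-0.8, 0)"
    for (p in seq_len(max(set@lengthClass))) {
      r <- pairwisePositionDecoding(session, p, win, nBoot = nBoot,
                                    maxPairs = maxPairs)
      summary[paste0("auc_position_", p)] <- r$meanAUC
      summary[paste0("p_position_", p)] <- r$p
      detail[[paste0("position_", p)]] <- r$perPair
    }
    summary["p_fdr_max"] <- max(bhFdr(
      summary[grep("^p_position_", names(summary))])$adjusted)
  }

  if (scenario == "fig2_geometry_encoding") {
    win <- epochWindow("go_cue", -0.7, 0)
    log$window <- "go_cue [-0.7, 0)"
    g23 <- crossPositionGeneralization(session, 3L, 2L, win, nBoot = nBoot)
    g32 <- crossPositionGeneralization(session, 2L, 3L, win, nBoot = nBoot)
    summary["auc_within_3"] <- g23$aucWithin
    summary["auc_cross_3to2"] <- g23$aucCross
    summary["normgen_2_3"] <- g23$normalizedGeneralization
    summary["normgen_3_2"] <- g32$normalizedGeneralization
    ## encoding model on tuned features
    ext <- extractWindows(session, win, mode = "average")
    labs <- trialLabels(session)[ext$trials]
    tuned <- rep(TRUE, nFeatures(session))
    if (!isTRUE(config$shuffleLabels)) {
      kw <- lapply(seq_len(max(set@lengthClass)), function(p)
        tuningTests(session, win, p, test = "kruskal")$rejected)
      anyTuned <- Reduce(`|`, kw)
      if (sum(anyTuned) >= 4L) tuned <- anyTuned
    }
    log$nTunedFeatures <- sum(tuned)
    fit <- fitEncodingModel(set, labs, ext$matrix[, tuned, drop = FALSE],
                            nPerm = nPerm)
    summary["encoding_r2_condavg"] <- fit$conditionAveragedR2
    summary["encoding_r2_single"] <- fit$singleTrialR2
    if (nPerm > 0) summary["encoding_p"] <- fit$permutation$pConditionAveraged
    cs <- coefficientSimilarity(set, labs, ext$matrix[, tuned, drop = FALSE])
    for (i in seq_len(nrow(cs$summary)))
      summary[paste0("cosine_", cs$summary$slotA[i], "_", cs$summary$slotB[i])] <-
        cs$summary$meanCosine[i]
    detail$cosine <- cs$summary
    ## displacement geometry in the position-3 discriminant plane
    geo <- tryCatch({
      splitIdx <- cvFolds(slotConsonant(set, labs, 3L), "stratified", k = 2L)
      train <- splitIdx == 1L
      m3 <- fitDiagLDA(ext$matrix[train, , drop = FALSE],
                       slotConsonant(set, labs[train], 3L))
      proj <- ldaProject(m3, ext$matrix[!train, , drop = FALSE],
                         components = 1:2)
      base <- marginalMeans(proj, set, labs[!train], keepSlots = 3L)
      ref <- marginalMeans(proj, set, labs[!train], keepSlots = c(2L, 3L))
      disp <- displacementVectors(base, ref)
      list(planeVar = planeVariance2D(ref$means), displacement = disp)
    }, error = function(e) NULL)
    if (!is.null(geo)) {
      summary["plane_variance_2d"] <- geo$planeVar
      detail$displacement <- geo$displacement
    }
  }

  if (scenario == "fig3_length") {
    win <- epochWindow("go_cue", -0.6, 0)
    log$window <- "go_cue [-0.6, 0)"
    sl <- sequenceLengthDecoding(session, win, nPerm = nPerm)
    summary["length_normalized_ba"] <- sl$normalizedBA
    if (nPerm > 0) summary["length_p"] <- sl$permutation$p
    ## joint length x first-phoneme LDA, 60/40 split, compositional predictor
    ext <- extractWindows(session, win, mode = "average")
    labs <- trialLabels(session)[ext$trials]
    lenLab <- as.character(set@lengthClass[labs])
    phoLab <- slotConsonant(set, labs, 1L)
    joint <- paste(lenLab, phoLab, sep = "|")
    fold <- cvFolds(joint, "stratified", k = 5L)
    train <- fold <= 3L          # 60% train, 40% held out
    model <- fitDiagLDA(ext$matrix[train, , drop = FALSE], joint[train])
    proj <- ldaProject(model, ext$matrix[!train, , drop = FALSE])
    cp <- compositionalPredict(proj, lenLab[!train], phoLab[!train],
                               nPerm = nPerm, nBoot = nBoot)
    summary["compositional_r2_condavg"] <- cp$conditionAveragedR2
    summary["compositional_r2_single"] <- cp$singleTrialR2
    if (nPerm > 0) summary["compositional_p"] <- cp$permutation$p
    detail$confusion <- sl$confusion
  }

  if (scenario == "fig4_generalization") {
    r <- crossEpochGeneralization(session, 1L, maxPairs = maxPairs)
    summary["auc_cue_cue"] <- r$auc[["cue"]]
    summary["auc_cue_prep"] <- r$auc[["prep"]]
    summary["auc_cue_speech"] <- r$auc[["speech"]]
    detail$perPair <- r$perPair
    log$peaks <- as.list(r$peaks)
  }

  if (scenario == "fig5_words_boundary") {
    r <- wordBoundaryAnalysis(session, maxPairs = maxPairs)
    summary["boundary_auc"] <- r$boundary$meanAUC
    summary["boundary_p"] <- r$boundary$p
    summary["late_auc_one_word"] <- r$latePosition$aucOneWord
    summary["late_auc_two_word"] <- r$latePosition$aucTwoWord
    summary["late_delta_p"] <- r$latePosition$pDelta
    detail$latePosition <- r$latePosition
  }

  res <- list(scenario = scenario, seed = seed, summary = summary,
              detail = detail, log = log)
  class(res) <- "ScenarioResult"
  if (!is.null(outDir)) writeScenarioFiles(res, outDir)
  res
}

writeScenarioFiles <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(as.list(res$summary),
                       file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(res$log, file.path(outDir, "log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(res$detail)) {
    d <- res$detail[[nm]]
    if (is.data.frame(d))
      write.csv(d, file.path(outDir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(outDir)
}

#' Write a human-readable scenario report
#'
#' Tabulates the scenario's summary quantities (AUC, R^2, cosine, p-values
#' with their resolution floors) into a plain-text report whose every
#' number is traceable to the JSON summary.
#'
#' @param res a `"ScenarioResult"` from [runScenario()]
#' @param path output text file
#' @return `path`, invisibly
#' @export
writeScenarioReport <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("phonoplan scenario report:", res$scenario),
    paste("seed:", res$seed),
    ""), con)
  if (length(res$summary)) {
    writeLines(sprintf("  %-28s %s", names(res$summary),
                       vapply(res$summary, function(v)
                         formatC(v, digits = 4, format = "g"), character(1))),
               con)
  } else writeLines("  (no summary quantities)", con)
  invisible(path)
}
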