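## Preprocessing: session z-scoring, Gaussian PSTH smoothing, and epoch /
## sliding-window feature extraction. Time convention: all window times are
## seconds relative to an alignment event; bins are half-open [start,
## start + binWidth) with bin 0 starting at the event, so a bin starting
## exactly at `end` is excluded.

#' An epoch window relative to a trial event
#'
#' @param alignEvent one of `"cue_onset"`, `"cue_offset"`, `"go_cue"`,
#'   `"speech_onset"`.
#' @param start,end window bounds in seconds relative to the event,
#'   half-open `[start, end)`.
#' @return a list of class `"EpochWindow"`.
#' @export
epochWindow <- function(alignEvent = c("cue_onset", "cue_offset", "go_cue",
                                       "speech_onset"),
                        start, end) {
  alignEvent <- match.arg(alignEvent)
  if (end <= start) stop("end must exceed start")
  structure(list(alignEvent = alignEvent, start = start, end = end),
            class = "EpochWindow")
}

#' Z-score a session against its whole-session statistics
#'
#' Each feature is centered and scaled by its mean and standard deviation
#' over all bins of all trials. With `blockSubtract = TRUE` the per-block
#' feature means are removed first, emulating per-block mean subtraction
#' that counteracts slow session drift. Zero-variance features pass through
#' as all zeros.
#'
#' @param session a [SessionData-class]
#' @param blockSubtract remove per-block feature means first?
#' @return the z-scored [SessionData-class]
#' @export
zscoreSession <- function(session, blockSubtract = FALSE) {
  if (nTrials(session) < 1L) stop("session is empty")
  x <- session@features
  d <- dim(x)
  flat <- matrix(x, d[1] * d[2], d[3])   # (trial,bin) rows x feature cols
  if (blockSubtract) {
    blk <- rep(session@blockIds, times = d[2])
    for (b in unique(blk)) {
      rows <- blk == b
      flat[rows, ] <- sweep(flat[rows, , drop = FALSE], 2L,
                            colMeans(flat[rows, , drop = FALSE]))
    }
  }
  mu <- colMeans(flat)
  sdv <- sqrt(colMeans(sweep(flat, 2L, mu)^2))
  sdv[sdv == 0] <- Inf                   # zero-variance -> all-zero output
  flat <- sweep(sweep(flat, 2L, mu), 2L, sdv, "/")
  session@features <- array(flat, dim = d)
  session
}

## truncated (+/- 4 sigma), edge-renormalized Gaussian smoothing along bins.
## x: bins x series matrix. Returns same shape.
gaussSmoothMatrix <- function(x, sigmaBins) {
  if (sigmaBins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigmaBins))
  k <- exp(-0.5 * ((-half:half) / sigmaBins)^2)
  k <- k / sum(k)
  nb <- nrow(x)
  xp <- rbind(matrix(0, half, ncol(x)), x, matrix(0, half, ncol(x)))
  num <- apply(xp, 2L, function(col) stats::filter(col, k, sides = 2))
  ones <- c(rep(0, half), rep(1, nb), rep(0, half))
  den <- stats::filter(ones, k, sides = 2)
  keep <- (half + 1L):(half + nb)
  sweep(matrix(num[keep, ], nb, ncol(x)), 1L, den[keep], "/")
}

#' Condition-averaged smoothed traces with bootstrap confidence bands
#'
#' Gaussian-smooths each trial's per-feature trace (sigma in ms, kernel
#' truncated at four sigma and renormalized at the edges), averages over the
#' trials of a condition group within an aligned window, and attaches a
#' percentile bootstrap confidence interval of the mean over trials.
#'
#' @param session a [SessionData-class]
#' @param trials integer or logical index selecting the group's trials
#' @param window an [epochWindow()]
#' @param sigmaMs Gaussian kernel standard deviation in milliseconds
#' @param nBoot bootstrap resamples of trials for the CI (0 disables)
#' @param level confidence level
#' @return list with `time` (bin start times relative to the event), `mean`
#'   (bins x features), `lower`/`upper` CI arrays, and `nTrials`
#' @export
smoothPSTH <- function(session, trials, window, sigmaMs = 60,
                       nBoot = 10000L, level = 0.95) {
  trials <- seq_len(nTrials(session))[trials]
  if (!length(trials)) stop("empty group: no trials selected")
  if (nBoot > 0L && length(trials) < 2L)
    stop("empty group: need >= 2 trials for a bootstrap CI")
  sigmaBins <- sigmaMs / 1000 / session@binWidth
  ext <- extractWindows(session, window, mode = "bins", trials = trials,
                        smoothSigmaBins = sigmaBins)
  sm <- ext$tensor                       # trials x bins x features
  d <- dim(sm)
  avg <- apply(sm, c(2L, 3L), mean)
  out <- list(time = ext$time, mean = avg, nTrials = d[1])
  if (nBoot > 0L) {
    flat <- matrix(sm, d[1], d[2] * d[3])
    bootIdx <- matrix(sample.int(d[1], d[1] * nBoot, replace = TRUE), nBoot, d[1])
    W <- matrix(0, nBoot, d[1])
    for (r in seq_len(nBoot)) {
      tab <- tabulate(bootIdx[r, ], nbins = d[1])
      W[r, ] <- tab / d[1]
    }
    bootMeans <- W %*% flat              # nBoot x (bins*features)
    a <- (1 - level) / 2
    qs <- apply(bootMeans, 2L, quantile, probs = c(a, 1 - a), names = FALSE)
    out$lower <- matrix(qs[1, ], d[2], d[3])
    out$upper <- matrix(qs[2, ], d[2], d[3])
  }
  out
}

#' Extract averaged or sliding-window features from a session
#'
#' In `"average"` mode, bins whose start time falls inside the half-open
#' aligned window are averaged, yielding a trials x features matrix. In
#' `"sliding"` mode, windows of `widthMs` advance in steps of `stepMs` from
#' the window start while they still fit, each yielding such a matrix. In
#' `"bins"` mode the raw (optionally smoothed) per-bin tensor is returned.
#' Trials whose recording does not cover the window are dropped and counted
#' (`nDropped`).
#'
#' @param session a [SessionData-class]
#' @param window an [epochWindow()]
#' @param mode `"average"`, `"sliding"` or `"bins"`
#' @param widthMs,stepMs sliding-window width and step (ms)
#' @param trials optional trial subset (default: all labeled trials)
#' @param smoothSigmaBins optional Gaussian smoothing (bins mode only)
#' @return `"average"`: list(`matrix`, `trials`, `nDropped`);
#'   `"sliding"`: list(`windows` = list of such lists, `starts`);
#'   `"bins"`: list(`tensor`, `time`, `trials`, `nDropped`)
#' @export
extractWindows <- function(session, window, mode = c("average", "sliding", "bins"),
                           widthMs = 100, stepMs = 60, trials = NULL,
                           smoothSigmaBins = 0) {
  mode <- match.arg(mode)
  if (is.null(trials)) trials <- which(!is.na(session@labels))
  trials <- seq_len(nTrials(session))[trials]
  ev <- session@events[[window$alignEvent]][trials]
  keepEv <- !is.na(ev)
  binW <- session@binWidth
  nBin <- nBins(session)
  eps <- 1e-9

  if (mode == "sliding") {
    width <- widthMs / 1000
    step <- stepMs / 1000
    starts <- seq(window$start, window$end - width + eps, by = step)
    starts <- starts[starts + width <= window$end + eps]
    wins <- lapply(starts, function(s0)
      extractWindows(session, epochWindow(window$alignEvent, s0, s0 + width),
                     mode = "average", trials = trials))
    return(list(starts = starts, windows = wins))
  }

  ## bin indices per trial for [start, end): bin b starts at (b-1)*binW and
  ## is included iff its start lies in the half-open window
  first <- ceiling((ev + window$start) / binW - eps) + 1L
  nb <- max(1L, round((window$end - window$start) / binW))
  last <- first + nb - 1L
  covered <- keepEv & first >= 1L & last <= nBin
  if (!any(covered)) stop("empty selection: no trial covers the window")
  use <- trials[covered]
  f1 <- first[covered]; l1 <- last[covered]
  nDropped <- sum(!covered)

  if (mode == "average") {
    mat <- t(vapply(seq_along(use), function(i) {
      colMeans(matrix(session@features[use[i], f1[i]:l1[i], ], nrow = nb))
    }, numeric(nFeatures(session))))
    return(list(matrix = mat, trials = use, nDropped = nDropped))
  }

  ## bins mode: rectangular tensor of the aligned window
  tens <- array(0, dim = c(length(use), nb, nFeatures(session)))
  for (i in seq_along(use)) {
    sl <- matrix(session@features[use[i], f1[i]:l1[i], ], nrow = nb)
    if (smoothSigmaBins > 0) sl <- gaussSmoothMatrix(sl, smoothSigmaBins)
    tens[i, , ] <- sl
  }
  time <- window$start + (seq_len(nb) - 1L) * binW
  list(tensor = tens, time = time, trials = use, nDropped = nDropped)
}
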