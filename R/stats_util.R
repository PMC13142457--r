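## Electrode-level hypothesis tests, FDR control and resampling primitives.

## vectorized Welch two-sample t-test over feature columns
welchColumns <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2L, var); v2 <- apply(X2, 2L, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  ## Welch-Satterthwaite degrees of freedom
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(delta = m1 - m2, seDelta = sqrt(se2), t = tstat, df = df, p = p)
}

#' Per-feature tuning tests on window-summed activity
#'
#' Tests, feature by feature, whether activity in an aligned window differs
#' across condition groups: Welch's unequal-variance t-test for two groups
#' (also reporting the difference of means and its propagated standard
#' error `sqrt(s1^2/n1 + s2^2/n2)`), or the Kruskal-Wallis nonparametric
#' one-way test for two or more groups.
#'
#' @param session a [SessionData-class]
#' @param window an [epochWindow()]
#' @param grouping vector assigning a group to every trial (`NA` trials are
#'   excluded); or the name of a slot position as integer to group by the
#'   consonant at that slot.
#' @param test `"welch"` (exactly 2 groups) or `"kruskal"`
#' @param alpha significance level for the corrected rejection mask
#' @param correct apply Benjamini-Hochberg FDR across features?
#' @return list of class `"TuningTestResult"`: `p`, `rejected`, `adjusted`,
#'   plus `delta` and `seDelta` in Welch mode; degenerate features carry
#'   `NA` p-values.
#' @export
tuningTests <- function(session, window, grouping, test = c("welch", "kruskal"),
                        alpha = 0.05, correct = TRUE) {
  test <- match.arg(test)
  if (length(grouping) == 1L && is.numeric(grouping))
    grouping <- slotConsonant(conditionSet(session),
                              trialLabels(session), as.integer(grouping))
  ext <- extractWindows(session, window, mode = "average",
                        trials = which(!is.na(grouping)))
  g <- factor(grouping[ext$trials])
  X <- ext$matrix * 1  # window-averaged activity
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(table(g) < 2L)) stop("need >= 2 trials per group")
  out <- list(test = test, groups = levels(g))
  if (test == "welch") {
    if (nlevels(g) != 2L) stop("welch mode needs exactly 2 groups")
    w <- welchColumns(X[g == levels(g)[1L], , drop = FALSE],
                      X[g == levels(g)[2L], , drop = FALSE])
    out$p <- w$p; out$delta <- w$delta; out$seDelta <- w$seDelta
    out$t <- w$t; out$df <- w$df
  } else {
    out$p <- apply(X, 2L, function(col) {
      if (length(unique(col)) < 2L) return(NA_real_)
      kruskal.test(col, g)$p.value
    })
  }
  if (correct) {
    fdr <- bhFdr(out$p, alpha = alpha)
    out$adjusted <- fdr$adjusted
    out$rejected <- fdr$rejected
  } else {
    out$adjusted <- out$p
    out$rejected <- !is.na(out$p) & out$p < alpha
  }
  class(out) <- "TuningTestResult"
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR procedure over a family of p-values. The family is always
#' passed explicitly (e.g. channels x cues, channels x positions); `NA`
#' entries are carried through unrejected.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA allowed)
#' @param alpha target FDR level
#' @return list with `rejected` logical mask and `adjusted` p-values
#'   (monotone nondecreasing in rank order)
#' @export
bhFdr <- function(pvalues, alpha = 0.05) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("input error: p-values must lie in [0, 1]")
  adjusted <- rep(NA_real_, length(pvalues))
  adjusted[ok] <- p.adjust(pvalues[ok], method = "BH")
  list(rejected = !is.na(adjusted) & adjusted <= alpha, adjusted = adjusted)
}

#' Percentile bootstrap confidence interval
#'
#' @param data vector, matrix or data.frame of units to resample (rows)
#' @param statistic function(resampled data) -> scalar
#' @param nBoot number of resamples
#' @param level confidence level
#' @param seed optional integer seed
#' @return list with `lower`, `upper`, `level`, `nBoot`, `nDropped`
#'   (resamples on which the statistic was undefined), and the bootstrap
#'   `draws`
#' @export
bootstrapCI <- function(data, statistic, nBoot = 10000L, level = 0.95,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 1L) stop("data must be non-empty")
  take <- function(idx) if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  draws <- vapply(seq_len(nBoot), function(r) {
    v <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                  error = function(e) NA_real_)
    if (length(v) != 1L) NA_real_ else as.numeric(v)
  }, numeric(1))
  nDropped <- sum(is.na(draws))
  a <- (1 - level) / 2
  q <- quantile(draws, probs = c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(lower = q[1], upper = q[2], level = level, nBoot = nBoot,
       nDropped = nDropped, draws = draws)
}

#' Label-shuffling permutation test
#'
#' One-sided permutation p-value defined as the raw fraction of permuted
#' statistics at least as extreme as the observed one (no +1 smoothing);
#' the minimum resolvable p (`1 / nPerm`) is reported alongside so that
#' values of 0 can be stated as `p < 1/nPerm`.
#'
#' @param data data object passed through to `statistic`
#' @param labels label vector to permute
#' @param statistic function(data, labels) -> scalar
#' @param nPerm number of permutations
#' @param alternative `"greater"` (observed large under the alternative) or
#'   `"less"`
#' @param seed optional integer seed
#' @return list with `p`, `observed`, `null` (permuted draws), `pFloor`,
#'   and `degenerate` (TRUE when the statistic is constant under all
#'   permutations)
#' @export
permutationTest <- function(data, labels, statistic, nPerm = 10000L,
                            alternative = c("greater", "less"), seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  obs <- statistic(data, labels)
  null <- vapply(seq_len(nPerm), function(r)
    statistic(data, labels[sample.int(length(labels))]), numeric(1))
  p <- if (alternative == "greater") mean(null >= obs) else mean(null <= obs)
  list(p = p, observed = obs, null = null, pFloor = 1 / nPerm,
       degenerate = isTRUE(all(null == null[1]) && null[1] == obs))
}
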