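## Per-cohort fusion accounting, per-sample fusion burden and the
## specimen-age effect analysis.

.confRank <- function(conf) match(conf, .CONFIDENCE_LEVELS) # low=1 < medium=2 < high=3

#' Deduplicate fusion calls within samples
#'
#' When the same fusion (same canonical key) is reported multiple times for
#' one sample, a single call is retained: the one with the highest
#' confidence, then the highest number of supporting reads (split_reads1 +
#' split_reads2 + discordant_mates), then the first occurrence in input
#' order. Rows from different samples never compete.
#'
#' @param calls data.frame of fusion calls ([readFusionTable()] columns).
#' @return data.frame with at most one row per (sample_id, key), in input
#'   order of the retained rows.
#' @export
dedupSampleFusions <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  support <- calls$split_reads1 + calls$split_reads2 + calls$discordant_mates
  ord <- order(
    calls$sample_id, calls$key,
    -.confRank(calls$confidence), -support, seq_len(nrow(calls))
  )
  sorted <- calls[ord, , drop = FALSE]
  keep <- !duplicated(paste(sorted$sample_id, sorted$key, sep = "\r"))
  out <- sorted[keep, , drop = FALSE]
  out <- out[order(match(rownames(out), rownames(calls))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_columns") <- attr(calls, "source_columns")
  out
}

#' Per-cohort fusion summary
#'
#' Reproduces the per-cohort accounting of fusion numbers by confidence
#' level. The `all` row counts distinct (sample, key) pairs; each confidence
#' row counts distinct (sample, key) pairs observed at that level, so a
#' fusion reported at two levels in one sample contributes to both level
#' rows (level percentages therefore need not sum to 100). `n_unique` counts
#' each key once per cohort. Means divide by the cohort sample size
#' (including samples without calls).
#'
#' @param x a [FusionCallSet-class].
#' @return data.frame with rows `all`, `high`, `medium`, `low` and columns
#'   `n_fusions`, `mean_per_sample`, `n_unique`, `pct_of_all`.
#' @export
setGeneric("summarizeCohort", function(x) standardGeneric("summarizeCohort"))

#' @rdname summarizeCohort
#' @export
setMethod("summarizeCohort", "FusionCallSet", function(x) {
  n <- nSamples(x)
  if (n == 0L) stop("cohort has zero samples")
  calls <- x@calls
  pairAll <- unique(paste(calls$sample_id, calls$key, sep = "\r"))
  nAll <- length(pairAll)
  rows <- list(all = list(
    n_fusions = nAll,
    mean_per_sample = nAll / n,
    n_unique = length(unique(calls$key)),
    pct_of_all = 100
  ))
  for (lev in c("high", "medium", "low")) {
    sub <- calls[calls$confidence == lev, , drop = FALSE]
    nLev <- length(unique(paste(sub$sample_id, sub$key, sep = "\r")))
    rows[[lev]] <- list(
      n_fusions = nLev,
      mean_per_sample = nLev / n,
      n_unique = length(unique(sub$key)),
      pct_of_all = if (nAll) 100 * nLev / nAll else NA_real_
    )
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- names(rows)
  out
})

.scopeCalls <- function(analysis, scope, combinedKeys = NULL) {
  switch(scope,
    all = analysis,
    high_only = analysis[analysis$confidence == "high", , drop = FALSE],
    combined = {
      if (is.null(combinedKeys))
        stop("confidence scope 'combined' requires the confirmation cohort's combined key set")
      analysis[analysis$key %in% combinedKeys, , drop = FALSE]
    },
    stop(sprintf("unknown confidence scope '%s'", scope))
  )
}

#' Per-sample fusion burden
#'
#' Burden is the number of distinct deduplicated fusions per sample within
#' the chosen confidence scope: `high_only` (high-confidence calls only),
#' `all` (any confidence), or `combined` (calls whose key belongs to the
#' confirmation cohort's combined set, any confidence; pass the set via
#' `combinedKeys`). Samples listed in the clinical table but absent from the
#' calls receive burden 0 and enter the median.
#'
#' @param x a [FusionCallSet-class].
#' @param scope `"high_only"`, `"combined"` or `"all"`.
#' @param clinical optional clinical data.frame whose `sample_id`s define
#'   the sample universe; defaults to the samples present in the calls.
#' @param combinedKeys character vector of combined keys (scope
#'   `"combined"` only), e.g. `combinedKeys(set)` from
#'   [buildCandidateSets()].
#' @return list with `burden` (data.frame `sample_id`, `burden`),
#'   `median_burden` and `confidence_scope`.
#' @export
setGeneric("perSampleBurden", function(x, scope = "high_only", clinical = NULL,
                                       combinedKeys = NULL) {
  standardGeneric("perSampleBurden")
})

#' @rdname perSampleBurden
#' @export
setMethod("perSampleBurden", "FusionCallSet", function(x, scope = "high_only",
                                                       clinical = NULL,
                                                       combinedKeys = NULL) {
  analysis <- .scopeCalls(x@analysisCalls, scope, combinedKeys)
  universe <- if (!is.null(clinical)) {
    as.character(clinical$sample_id)
  } else {
    unique(x@calls$sample_id)
  }
  counts <- table(factor(analysis$sample_id, levels = universe))
  burden <- data.frame(
    sample_id = universe,
    burden = as.integer(counts),
    stringsAsFactors = FALSE
  )
  list(
    burden = burden,
    median_burden = stats::median(burden$burden),
    confidence_scope = scope
  )
})

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test on the sum of ranks of `x` within the pooled
#' sample. When both groups have at most `exactMax` observations the p-value
#' is computed by exhaustive enumeration of all group assignments (valid
#' under ties); otherwise the normal approximation with tie correction and
#' continuity correction is used. Extremity is measured as distance of the
#' rank sum from its permutation mean.
#'
#' @param x,y numeric vectors.
#' @param exactMax enumeration threshold per group (default 10).
#' @param alternative `"two.sided"` (default) or `"greater"` (`x` tends to
#'   larger values).
#' @return list with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
rankSumTest <- function(x, y, exactMax = 10L,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x); ny <- length(y); n <- nx + ny
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (nx <= exactMax && ny <= exactMax) {
    combs <- utils::combn(n, nx)
    sums <- colSums(matrix(r[combs], nrow = nx))
    eps <- sqrt(.Machine$double.eps)
    p <- if (alternative == "two.sided") {
      mean(abs(sums - mu) >= abs(W - mu) - eps)
    } else {
      mean(sums >= W - eps)
    }
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else if (alternative == "two.sided") {
      z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    } else {
      z <- (W - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = W, p.value = p, method = method)
}

#' Specimen-age group comparison of fusion burden
#'
#' Splits samples into `nGroups` specimen-age groups at empirical quantiles
#' (default tertiles; ties go to the lower group) and compares the fusion
#' burden of the youngest group against all older samples with a two-sided
#' Wilcoxon rank-sum test ([rankSumTest()]).
#'
#' @param burdens result of [perSampleBurden()] (or its `burden` data.frame).
#' @param clinical clinical data.frame providing `specimen_age` per sample.
#' @param nGroups number of age groups (default 3).
#' @return list with `groups` (data.frame `sample_id`, `specimen_age`,
#'   `group` 1 = youngest), `cutpoints`, and the `test` result.
#' @export
ageGroupComparison <- function(burdens, clinical, nGroups = 3L) {
  bt <- if (is.data.frame(burdens)) burdens else burdens$burden
  idx <- match(bt$sample_id, clinical$sample_id)
  if (any(is.na(idx)))
    stop(sprintf(
      "samples missing from clinical table: %s",
      paste(bt$sample_id[is.na(idx)], collapse = ", ")
    ))
  age <- clinical$specimen_age[idx]
  if (any(is.na(age)))
    stop(sprintf(
      "specimen_age missing for sample(s): %s",
      paste(bt$sample_id[is.na(age)], collapse = ", ")
    ))
  probs <- seq_len(nGroups - 1L) / nGroups
  cut <- stats::quantile(age, probs = probs, names = FALSE)
  group <- 1L + rowSums(outer(age, cut, `>`)) # ties (age == cutpoint) stay low
  groups <- data.frame(
    sample_id = bt$sample_id, specimen_age = age,
    group = as.integer(group), stringsAsFactors = FALSE
  )
  young <- bt$burden[group == 1L]
  older <- bt$burden[group > 1L]
  if (!length(young) || !length(older))
    stop("age grouping produced an empty comparison group")
  list(
    groups = groups,
    cutpoints = cut,
    test = rankSumTest(young, older)
  )
}
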