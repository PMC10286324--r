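## Discovery/confirmation cross-cohort workflow: candidate sets, overlap and
## ranking against a known-fusion catalog, novelty calls, and per-gene
## fusion-status concordance.

.cohortLevelKeySets <- function(fcs) {
  calls <- fusionCalls(fcs)
  lapply(stats::setNames(nm = c("high", "medium", "low")), function(lev) {
    unique(calls$key[calls$confidence == lev])
  })
}

#' Build per-cohort candidate fusion sets
#'
#' Discovery and evaluation cohorts contribute their cohort-unique
#' high-confidence key sets. Each confirmation cohort (typically FFPE, where
#' RNA degradation depresses call confidence) gets a combined set: fusions it
#' detected at any confidence that match the union of the discovery cohorts'
#' high-confidence fusions, plus all of its own remaining high-confidence
#' fusions.
#'
#' @param cohorts list of [FusionCallSet-class] objects; at least one must
#'   have role `"discovery"`.
#' @return list of [CohortFusionSet-class] objects, one per input cohort.
#' @export
buildCandidateSets <- function(cohorts) {
  roles <- vapply(cohorts, cohortRole, character(1))
  if (!any(roles == "discovery"))
    stop("at least one discovery cohort is required")
  levelSets <- lapply(cohorts, .cohortLevelKeySets)
  discoveryHigh <- unique(unlist(
    lapply(levelSets[roles == "discovery"], `[[`, "high")
  ))
  mapply(function(fcs, ls) {
    role <- cohortRole(fcs)
    combined <- if (role == "confirmation") {
      anyLevel <- unique(unlist(ls))
      union(intersect(anyLevel, discoveryHigh), ls$high)
    } else {
      character(0)
    }
    new("CohortFusionSet",
      name = cohortName(fcs), role = role,
      keysByLevel = ls, combinedKeys = combined
    )
  }, cohorts, levelSets, SIMPLIFY = FALSE)
}

#' Cross-cohort overlap and ranking
#'
#' Restricts fusions to those detected in at least `minCohorts` cohorts
#' (in the [detectedKeys()] sense), flags exact catalog membership, and
#' ranks: fusions are grouped by known status (unknown first by default),
#' then by descending number of cohorts, then by rediscovery in a
#' confirmation cohort, then lexicographically (stable).
#'
#' @param sets list of [CohortFusionSet-class] from [buildCandidateSets()].
#' @param catalog a [KnownFusionCatalog-class].
#' @param minCohorts minimum number of cohorts a fusion must appear in
#'   (default 2).
#' @param knownFirst if `TRUE`, known fusions sort before unknown ones
#'   (default `FALSE`: unknown first).
#' @param cohortCountFirst if `TRUE` (default) the cohort-count sort key
#'   precedes the confirmation-rediscovery flag.
#' @return data.frame with columns `key`, one 0/1 column per cohort,
#'   `known`, `n_cohorts`.
#' @export
overlapAndRank <- function(sets, catalog, minCohorts = 2L,
                           knownFirst = FALSE, cohortCountFirst = TRUE) {
  if (length(sets) < 2L) stop("need at least two cohort fusion sets")
  nms <- vapply(sets, cohortName, character(1))
  det <- lapply(sets, detectedKeys)
  keys <- sort(unique(unlist(det)))
  flags <- vapply(det, function(k) as.integer(keys %in% k), integer(length(keys)))
  flags <- matrix(flags, nrow = length(keys), dimnames = list(NULL, nms))
  nCoh <- rowSums(flags)
  keep <- nCoh >= minCohorts
  out <- data.frame(key = keys[keep], stringsAsFactors = FALSE)
  for (j in seq_along(nms)) out[[nms[j]]] <- flags[keep, j]
  out$known <- out$key %in% catalogEntries(catalog)
  out$n_cohorts <- as.integer(nCoh[keep])

  confirmCols <- nms[vapply(sets, cohortRole, character(1)) == "confirmation"]
  redisc <- if (length(confirmCols)) {
    as.integer(rowSums(out[, confirmCols, drop = FALSE]) > 0)
  } else {
    rep(0L, nrow(out))
  }
  knownKey <- if (knownFirst) !out$known else out$known
  ordKeys <- if (cohortCountFirst) {
    list(knownKey, -out$n_cohorts, -redisc, out$key)
  } else {
    list(knownKey, -redisc, -out$n_cohorts, out$key)
  }
  out <- out[do.call(order, ordKeys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Novel fusion candidates
#'
#' Fusions in an overlap table that are absent from the catalog and detected
#' in all cohorts (default) or in at least the table's minimum number of
#' cohorts.
#'
#' @param table overlap table from [overlapAndRank()].
#' @param requireAllCohorts if `TRUE` (default) the fusion must be flagged
#'   in every cohort column of the table.
#' @return character vector of keys, in table order.
#' @export
novelCandidates <- function(table, requireAllCohorts = TRUE) {
  cohortCols <- setdiff(names(table), c("key", "known", "n_cohorts"))
  sel <- !table$known
  if (requireAllCohorts) sel <- sel & table$n_cohorts == length(cohortCols)
  table$key[sel]
}

#' Per-gene fusion-status concordance
#'
#' Compares two per-sample boolean fusion-status vectors one-to-one (e.g.
#' this pipeline's calls vs. an externally published status for the same
#' gene) and builds the 2x2 contingency table.
#'
#' @param statusA,statusB named logical vectors over the same sample set.
#' @return list with `table` (2x2 matrix, rows = A, cols = B), `agreement`
#'   fraction, `pct_positive_A`, `pct_positive_B`, and `n`.
#' @export
geneStatusConcordance <- function(statusA, statusB) {
  if (is.null(names(statusA)) || is.null(names(statusB)))
    stop("statusA and statusB must be named by sample_id")
  onlyA <- setdiff(names(statusA), names(statusB))
  onlyB <- setdiff(names(statusB), names(statusA))
  if (length(onlyA) || length(onlyB))
    stop(sprintf(
      "sample sets differ: only in A: %s; only in B: %s",
      paste(onlyA, collapse = ", "), paste(onlyB, collapse = ", ")
    ))
  b <- statusB[names(statusA)]
  n <- length(statusA)
  tab <- matrix(
    c(
      sum(statusA & b), sum(statusA & !b),
      sum(!statusA & b), sum(!statusA & !b)
    ),
    nrow = 2, byrow = TRUE,
    dimnames = list(A = c("pos", "neg"), B = c("pos", "neg"))
  )
  list(
    table = tab,
    agreement = (tab["pos", "pos"] + tab["neg", "neg"]) / n,
    pct_positive_A = 100 * sum(statusA) / n,
    pct_positive_B = 100 * sum(b) / n,
    n = n
  )
}
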