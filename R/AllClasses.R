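#' @import methods
NULL

.CONFIDENCE_LEVELS <- c("low", "medium", "high")
.COHORT_ROLES <- c("discovery", "confirmation", "evaluation")
.PRESERVATIONS <- c("fresh_frozen", "FFPE")
.LIBRARIES <- c("totalRNA", "polyA")

#' Cohort configuration
#'
#' Describes one RNA-seq cohort: its role in the cross-cohort workflow
#' (discovery cohorts nominate high-confidence fusions, confirmation cohorts
#' re-detect them at any confidence, evaluation cohorts extend the overlap),
#' the specimen preservation type, the library protocol and the survival
#' endpoint label.
#'
#' @slot name cohort name.
#' @slot role one of `"discovery"`, `"confirmation"`, `"evaluation"`.
#' @slot preservation one of `"fresh_frozen"`, `"FFPE"`.
#' @slot library one of `"totalRNA"`, `"polyA"`.
#' @slot endpointLabel free-text endpoint label (e.g. `"BCR"`, `"DoD"`).
#' @slot nSamples number of distinct samples in the cohort.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    name = "character",
    role = "character",
    preservation = "character",
    library = "character",
    endpointLabel = "character",
    nSamples = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!object@role %in% .COHORT_ROLES)
    msg <- c(msg, sprintf("'role' must be one of %s", paste(.COHORT_ROLES, collapse = ", ")))
  if (!object@preservation %in% .PRESERVATIONS)
    msg <- c(msg, sprintf("'preservation' must be one of %s", paste(.PRESERVATIONS, collapse = ", ")))
  if (!object@library %in% .LIBRARIES)
    msg <- c(msg, sprintf("'library' must be one of %s", paste(.LIBRARIES, collapse = ", ")))
  if (length(object@nSamples) != 1L || is.na(object@nSamples) || object@nSamples < 1L)
    msg <- c(msg, "'nSamples' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' @param name cohort name.
#' @param role `"discovery"`, `"confirmation"` or `"evaluation"`.
#' @param preservation `"fresh_frozen"` or `"FFPE"`.
#' @param library `"totalRNA"` or `"polyA"`.
#' @param endpointLabel endpoint label, e.g. `"BCR"`.
#' @param nSamples number of distinct samples.
#' @return a [CohortConfig-class] object.
#' @examples
#' cohortConfig("FF_RP", "discovery", "fresh_frozen", "totalRNA", "DoD", 40)
#' @export
cohortConfig <- function(name, role, preservation, library = "totalRNA",
                         endpointLabel = "BCR", nSamples) {
  new("CohortConfig",
    name = as.character(name), role = as.character(role),
    preservation = as.character(preservation), library = as.character(library),
    endpointLabel = as.character(endpointLabel), nSamples = as.integer(nSamples)
  )
}

#' Fusion call set for one cohort
#'
#' Holds the raw fusion calls of a cohort together with the per-sample
#' deduplicated analysis set. Deduplication keeps, for each (sample, fusion
#' key) pair, the call with the highest confidence, then the highest number
#' of supporting reads (split reads plus discordant mates), then the first
#' occurrence in input order.
#'
#' @slot cohort a [CohortConfig-class].
#' @slot calls data.frame of raw calls (one row per reported call).
#' @slot analysisCalls data.frame after per-sample deduplication.
#' @exportClass FusionCallSet
setClass("FusionCallSet",
  representation(
    cohort = "CohortConfig",
    calls = "data.frame",
    analysisCalls = "data.frame"
  )
)

setValidity("FusionCallSet", function(object) {
  msg <- character()
  needed <- c("sample_id", "key", "confidence")
  for (df in list(object@calls, object@analysisCalls)) {
    miss <- setdiff(needed, names(df))
    if (length(miss))
      msg <- c(msg, sprintf("call table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!length(msg) && nrow(object@analysisCalls)) {
    id <- paste(object@analysisCalls$sample_id, object@analysisCalls$key, sep = "\r")
    if (anyDuplicated(id))
      msg <- c(msg, "analysisCalls must contain at most one call per (sample_id, key)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FusionCallSet
#'
#' @param cohort a [CohortConfig-class].
#' @param calls data.frame of fusion calls as returned by [readFusionTable()].
#' @return a [FusionCallSet-class]; the analysis set is computed by
#'   [dedupSampleFusions()] at construction time.
#' @export
fusionCallSet <- function(cohort, calls) {
  new("FusionCallSet",
    cohort = cohort, calls = calls,
    analysisCalls = dedupSampleFusions(calls)
  )
}

#' Known-fusion catalog
#'
#' A set of canonical fusion keys (`"G1::G2"`) regarded as already described,
#' e.g. a Mitelman-DB-like extract. Membership lookup is exact-string on
#' canonical keys.
#'
#' @slot entries character vector of canonical keys.
#' @slot sourceLabel provenance label for reporting.
#' @exportClass KnownFusionCatalog
setClass("KnownFusionCatalog",
  representation(entries = "character", sourceLabel = "character")
)

setValidity("KnownFusionCatalog", function(object) {
  if (anyDuplicated(object@entries)) "catalog entries must be unique" else TRUE
})

#' Construct a KnownFusionCatalog
#'
#' Entries are canonicalized (parenthesized caller distance annotations
#' stripped) before storage.
#'
#' @param entries character vector of fusion keys (`"G1::G2"`).
#' @param sourceLabel provenance label.
#' @return a [KnownFusionCatalog-class].
#' @export
knownFusionCatalog <- function(entries, sourceLabel = "user") {
  entries <- vapply(entries, .canonicalizeKeyString, character(1), USE.NAMES = FALSE)
  new("KnownFusionCatalog", entries = unique(entries), sourceLabel = sourceLabel)
}

#' Per-cohort fusion key sets for the cross-cohort workflow
#'
#' @slot name cohort name.
#' @slot role cohort role.
#' @slot keysByLevel named list (`high`, `medium`, `low`) of cohort-unique
#'   key sets per confidence level.
#' @slot combinedKeys the confirmation cohort's combined set (matched
#'   discovery fusions at any confidence plus its own high-confidence
#'   fusions); empty for other roles.
#' @exportClass CohortFusionSet
setClass("CohortFusionSet",
  representation(
    name = "character", role = "character",
    keysByLevel = "list", combinedKeys = "character"
  )
)

setValidity("CohortFusionSet", function(object) {
  msg <- character()
  if (!object@role %in% .COHORT_ROLES)
    msg <- c(msg, "invalid role")
  if (!all(c("high", "medium", "low") %in% names(object@keysByLevel)))
    msg <- c(msg, "keysByLevel must have entries high, medium, low")
  if (object@role != "confirmation" && length(object@combinedKeys))
    msg <- c(msg, "combinedKeys is defined only for confirmation cohorts")
  if (length(msg)) msg else TRUE
})

## -- accessors ---------------------------------------------------------------

#' @rdname CohortConfig-class
#' @param object,x object.
#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))
#' @rdname CohortConfig-class
#' @export
setMethod("cohortName", "CohortConfig", function(x) x@name)
#' @rdname CohortConfig-class
#' @export
setMethod("cohortName", "FusionCallSet", function(x) x@cohort@name)
#' @rdname CohortConfig-class
#' @export
setMethod("cohortName", "CohortFusionSet", function(x) x@name)

#' @rdname CohortConfig-class
#' @export
setGeneric("cohortRole", function(x) standardGeneric("cohortRole"))
#' @rdname CohortConfig-class
#' @export
setMethod("cohortRole", "CohortConfig", function(x) x@role)
#' @rdname CohortConfig-class
#' @export
setMethod("cohortRole", "FusionCallSet", function(x) x@cohort@role)
#' @rdname CohortConfig-class
#' @export
setMethod("cohortRole", "CohortFusionSet", function(x) x@role)

#' @rdname CohortConfig-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname CohortConfig-class
#' @export
setMethod("nSamples", "CohortConfig", function(x) x@nSamples)
#' @rdname CohortConfig-class
#' @export
setMethod("nSamples", "FusionCallSet", function(x) x@cohort@nSamples)

#' @rdname FusionCallSet-class
#' @param x a FusionCallSet.
#' @export
setGeneric("fusionCalls", function(x) standardGeneric("fusionCalls"))
#' @rdname FusionCallSet-class
#' @export
setMethod("fusionCalls", "FusionCallSet", function(x) x@calls)

#' @rdname FusionCallSet-class
#' @export
setGeneric("analysisCalls", function(x) standardGeneric("analysisCalls"))
#' @rdname FusionCallSet-class
#' @export
setMethod("analysisCalls", "FusionCallSet", function(x) x@analysisCalls)

#' @rdname FusionCallSet-class
#' @export
setGeneric("cohortConfigOf", function(x) standardGeneric("cohortConfigOf"))
#' @rdname FusionCallSet-class
#' @export
setMethod("cohortConfigOf", "FusionCallSet", function(x) x@cohort)

#' @rdname KnownFusionCatalog-class
#' @param x a KnownFusionCatalog.
#' @export
setGeneric("catalogEntries", function(x) standardGeneric("catalogEntries"))
#' @rdname KnownFusionCatalog-class
#' @export
setMethod("catalogEntries", "KnownFusionCatalog", function(x) x@entries)

#' @rdname CohortFusionSet-class
#' @param x a CohortFusionSet.
#' @export
setGeneric("keysByLevel", function(x) standardGeneric("keysByLevel"))
#' @rdname CohortFusionSet-class
#' @export
setMethod("keysByLevel", "CohortFusionSet", function(x) x@keysByLevel)

#' @rdname CohortFusionSet-class
#' @export
setGeneric("combinedKeys", function(x) standardGeneric("combinedKeys"))
#' @rdname CohortFusionSet-class
#' @export
setMethod("combinedKeys", "CohortFusionSet", function(x) x@combinedKeys)

#' Keys counting as "detected" in the cross-cohort sense
#'
#' Discovery and evaluation cohorts contribute their high-confidence key
#' sets; confirmation cohorts contribute their combined set.
#'
#' @param x a [CohortFusionSet-class].
#' @return character vector of keys.
#' @export
setGeneric("detectedKeys", function(x) standardGeneric("detectedKeys"))
#' @rdname detectedKeys
#' @export
setMethod("detectedKeys", "CohortFusionSet", function(x) {
  if (x@role == "confirmation") x@combinedKeys else x@keysByLevel$high
})

## -- show methods ------------------------------------------------------------

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig '%s': role=%s, preservation=%s, library=%s, endpoint=%s, n=%d\n",
    object@name, object@role, object@preservation, object@library,
    object@endpointLabel, object@nSamples
  ))
})

setMethod("show", "FusionCallSet", function(object) {
  cat(sprintf(
    "FusionCallSet '%s' (%s): %d raw calls, %d after per-sample dedup, %d samples with calls\n",
    object@cohort@name, object@cohort@role, nrow(object@calls),
    nrow(object@analysisCalls), length(unique(object@calls$sample_id))
  ))
})

setMethod("show", "KnownFusionCatalog", function(object) {
  cat(sprintf(
    "KnownFusionCatalog '%s': %d entries\n", object@sourceLabel,
    length(object@entries)
  ))
})

setMethod("show", "CohortFusionSet", function(object) {
  cat(sprintf(
    "CohortFusionSet '%s' (%s): high=%d medium=%d low=%d%s\n",
    object@name, object@role,
    length(object@keysByLevel$high), length(object@keysByLevel$medium),
    length(object@keysByLevel$low),
    if (object@role == "confirmation")
      sprintf(", combined=%d", length(object@combinedKeys)) else ""
  ))
})
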