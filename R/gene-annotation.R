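## Functional annotation of fusion partners: gene classes and prefix rules,
## snoRNA/host-gene fusions, read-through candidates, 5'/3' partner
## promiscuity, and hypergeometric gene-set enrichment.

#' Default symbol-prefix classification rules
#'
#' Used when a partner symbol is absent from the gene annotation: snRNAs
#' carry an `RNU` prefix, snoRNAs a `SNOR` prefix, and BAC-clone-derived
#' identifiers begin with `RP11`, `CTC-`, `AC0` or `LL0`.
#'
#' @return named list of regular expressions.
#' @export
defaultPrefixRules <- function() {
  list(
    snRNA = "^RNU",
    snoRNA = "^SNOR",
    clone_derived = "^(RP11|CTC-|AC0|LL0)"
  )
}

.expandComposite <- function(symbol) {
  unlist(strsplit(symbol, ",", fixed = TRUE), use.names = FALSE)
}

.classTag <- function(cls) {
  switch(cls,
    snoRNA = "snoRNA_partner",
    snRNA = "snRNA_partner",
    NULL
  )
}

#' Classify a fusion partner
#'
#' Tags a partner symbol by gene class and gene-set membership. Annotation
#' entries take precedence: `gene_class` snoRNA/snRNA map to the
#' corresponding partner tags, a non-empty `host_of` yields
#' `snoRNA_host_partner`, and every `gene_sets` label is emitted as a tag
#' (e.g. `ETS_family`). Symbols absent from the annotation fall back to the
#' prefix rules. Composite partners (`"A,B"`) are expanded and contribute
#' the union of their tags.
#'
#' @param symbol partner symbol (possibly composite).
#' @param annotation GRanges from [readGeneAnnotation()], or `NULL`.
#' @param prefixRules named list of regexes, see [defaultPrefixRules()].
#' @return character vector of tags (possibly empty).
#' @export
classifyPartner <- function(symbol, annotation = NULL,
                            prefixRules = defaultPrefixRules()) {
  tags <- character(0)
  for (sym in .expandComposite(symbol)) {
    hit <- !is.null(annotation) && sym %in% names(annotation)
    if (hit) {
      rec <- annotation[sym]
      cls <- S4Vectors::mcols(rec)$gene_class
      tags <- c(tags, .classTag(cls))
      if (length(S4Vectors::mcols(rec)$host_of[[1]]))
        tags <- c(tags, "snoRNA_host_partner")
      tags <- c(tags, S4Vectors::mcols(rec)$gene_sets[[1]])
    } else {
      if (grepl(prefixRules$snRNA, sym)) tags <- c(tags, "snRNA_partner")
      if (grepl(prefixRules$snoRNA, sym)) tags <- c(tags, "snoRNA_partner")
      if (grepl(prefixRules$clone_derived, sym)) tags <- c(tags, "clone_derived_partner")
    }
  }
  unique(tags)
}

#' Find snoRNA / host-gene fusions
#'
#' Returns fusions in which any partner is a snoRNA (by class or prefix) or
#' a snoRNA host gene (non-empty `host_of`). Fusions pairing an snRNA with a
#' snoRNA or host gene are additionally flagged (`snRNA_sno_type`).
#'
#' @param keys character vector of canonical fusion keys.
#' @param annotation GRanges from [readGeneAnnotation()].
#' @param prefixRules see [defaultPrefixRules()].
#' @return data.frame `key`, `tags` (semicolon-joined), `snRNA_sno_type`.
#' @export
findSnoFusions <- function(keys, annotation,
                           prefixRules = defaultPrefixRules()) {
  keys <- unique(keys)
  sides <- splitKey(keys)
  rows <- lapply(seq_along(keys), function(i) {
    t5 <- classifyPartner(paste(sides$genes5[[i]], collapse = ","), annotation, prefixRules)
    t3 <- classifyPartner(paste(sides$genes3[[i]], collapse = ","), annotation, prefixRules)
    tags <- unique(c(t5, t3))
    snoish <- function(tg) any(tg %in% c("snoRNA_partner", "snoRNA_host_partner"))
    if (!snoish(tags)) return(NULL)
    snType <- ("snRNA_partner" %in% t5 && snoish(t3)) ||
      ("snRNA_partner" %in% t3 && snoish(t5))
    data.frame(
      key = keys[i], tags = paste(sort(tags), collapse = ";"),
      snRNA_sno_type = snType, stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(
      key = character(0), tags = character(0),
      snRNA_sno_type = logical(0), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.partnerSpan <- function(symbols, annotation) {
  located <- symbols[symbols %in% names(annotation)]
  if (!length(located)) return(NULL)
  gr <- annotation[located]
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (length(chroms) != 1L) return(NULL) # alternatives on different chromosomes
  list(
    chrom = chroms,
    start = min(GenomicRanges::start(gr)),
    end = max(GenomicRanges::end(gr))
  )
}

#' Flag read-through fusion candidates
#'
#' A fusion is a read-through candidate when both partners lie on the same
#' chromosome and the gap between their gene spans (0 if they overlap) is at
#' most `maxGapBp` — transcription running from one gene into an adjacent
#' neighbor can then explain the chimeric transcript without a genomic
#' rearrangement. Composite partners use the span over their locatable
#' alternatives. Fusions with an unlocatable partner get `NA` and a warning.
#'
#' @param keys character vector of canonical keys.
#' @param annotation GRanges from [readGeneAnnotation()].
#' @param maxGapBp maximum inter-gene gap in bp (inclusive; default 2e5).
#' @return data.frame `key`, `chrom`, `gap_bp`, `readthrough_candidate`.
#' @export
readthroughCandidates <- function(keys, annotation, maxGapBp = 200000L) {
  keys <- unique(keys)
  sides <- splitKey(keys)
  res <- lapply(seq_along(keys), function(i) {
    s5 <- .partnerSpan(sides$genes5[[i]], annotation)
    s3 <- .partnerSpan(sides$genes3[[i]], annotation)
    if (is.null(s5) || is.null(s3)) {
      return(data.frame(
        key = keys[i], chrom = NA_character_, gap_bp = NA_integer_,
        readthrough_candidate = NA, stringsAsFactors = FALSE
      ))
    }
    if (s5$chrom != s3$chrom) {
      return(data.frame(
        key = keys[i], chrom = NA_character_, gap_bp = NA_integer_,
        readthrough_candidate = FALSE, stringsAsFactors = FALSE
      ))
    }
    gap <- max(0L, max(s5$start, s3$start) - min(s5$end, s3$end) - 1L)
    data.frame(
      key = keys[i], chrom = s5$chrom, gap_bp = as.integer(gap),
      readthrough_candidate = gap <= maxGapBp, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (anyNA(out$readthrough_candidate))
    warning(sprintf(
      "partner(s) not locatable for: %s",
      paste(out$key[is.na(out$readthrough_candidate)], collapse = ", ")
    ))
  rownames(out) <- NULL
  out
}

#' Partner promiscuity (most frequent 5' or 3' fusion genes)
#'
#' Counts, per cohort, the number of distinct deduplicated fusion events
#' (sample, key) in which each gene appears on the given side. A gene fused
#' in one sample via two different partners counts twice; the same key twice
#' counts once (deduplicated events). Composite partners contribute one
#' occurrence to each of their genes. The combined frequency pools cohorts:
#' sum of occurrences divided by the sum of sample sizes.
#'
#' @param cohorts list of [FusionCallSet-class] objects.
#' @param side `"5prime"` or `"3prime"`.
#' @return data.frame `gene`, one count and one frequency column per cohort,
#'   `combined_frequency`; sorted by `combined_frequency` descending.
#' @export
promiscuity <- function(cohorts, side = c("5prime", "3prime")) {
  side <- match.arg(side)
  nms <- vapply(cohorts, cohortName, character(1))
  ns <- vapply(cohorts, nSamples, integer(1))
  perCohort <- lapply(cohorts, function(fcs) {
    a <- analysisCalls(fcs)
    if (!nrow(a)) return(table(character(0)))
    sides <- splitKey(a$key)
    genes <- if (side == "5prime") sides$genes5 else sides$genes3
    ev <- rep(seq_len(nrow(a)), lengths(genes))
    g <- unlist(genes, use.names = FALSE)
    # one occurrence per (event, gene)
    uniq <- !duplicated(paste(ev, g, sep = "\r"))
    table(g[uniq])
  })
  genes <- sort(unique(unlist(lapply(perCohort, names))))
  if (!length(genes)) {
    return(data.frame(gene = character(0), combined_frequency = numeric(0)))
  }
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  tot <- rep(0, length(genes))
  for (j in seq_along(nms)) {
    cnt <- as.integer(perCohort[[j]][genes])
    cnt[is.na(cnt)] <- 0L
    out[[paste0("count_", nms[j])]] <- cnt
    out[[paste0("freq_", nms[j])]] <- cnt / ns[j]
    tot <- tot + cnt
  }
  out$combined_frequency <- tot / sum(ns)
  out <- out[order(-out$combined_frequency, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests over-representation of the query genes with the
#' hypergeometric upper tail P(X >= k) (k = overlap, K = set size, n = query
#' size, N = universe size) and adjusts across the sets tested in this call
#' with Benjamini-Hochberg.
#'
#' @param queryGenes character vector of query genes (subset of universe).
#' @param geneSets named list of character vectors (each a subset of the
#'   universe).
#' @param universe character vector of all genes considered.
#' @return data.frame `gene_set`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#' @export
geneSetEnrichment <- function(queryGenes, geneSets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  queryGenes <- unique(queryGenes)
  if (!all(queryGenes %in% universe))
    stop("query genes must be a subset of the universe")
  if (is.null(names(geneSets)) || any(!nzchar(names(geneSets))))
    stop("geneSets must be a named list")
  N <- length(universe)
  n <- length(queryGenes)
  rows <- lapply(names(geneSets), function(label) {
    set <- unique(geneSets[[label]])
    if (!all(set %in% universe))
      stop(sprintf("gene set '%s' is not a subset of the universe", label))
    K <- length(set)
    k <- length(intersect(queryGenes, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(
      gene_set = label, k = k, K = K, n = n, N = N, p = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
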