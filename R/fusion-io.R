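## Reading/validation of fusion-call tables (Arriba TSV dialect), clinical
## tables, known-fusion catalogs and gene annotation; canonical fusion
## identity used by every downstream stage.

.REQUIRED_FUSION_COLS <- c(
  "gene1", "gene2", "breakpoint1", "breakpoint2",
  "confidence", "split_reads1", "split_reads2", "discordant_mates"
)

## strips parenthesized groups containing only digits and commas (Arriba's
## distance-to-breakpoint annotations on alternative partner names); never
## touches other parentheses
.normalizeGeneName <- function(x) {
  out <- gsub("\\([0-9,]+\\)", "", x)
  parts <- strsplit(out, ",", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    paste(p, collapse = ",")
  }, character(1))
}

.canonicalizeKeyString <- function(key) {
  sides <- strsplit(key, "::", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop(sprintf("not a fusion key of the form 'G1::G2': '%s'", key))
  canonicalKey(sides[1], sides[2])
}

#' Canonical cohort-comparable fusion identity
#'
#' Builds the canonical key `"G1::G2"` (5' partner before 3' partner) from
#' caller-reported partner names. Parenthesized groups containing only digits
#' and commas (caller distance annotations such as `"MBTPS2(33,120)"`) are
#' stripped; comma-separated alternative partner names are retained in order
#' as a single composite partner. Order is preserved: `"A::B"` and `"B::A"`
#' are distinct fusions.
#'
#' @param gene1 character vector of 5' partner names.
#' @param gene2 character vector of 3' partner names.
#' @return character vector of canonical keys.
#' @examples
#' canonicalKey("TMPRSS2", "ERG")
#' canonicalKey("MBTPS2(33,120),LL0XNC01-39B3.1(20,917)", "SMS")
#' @export
canonicalKey <- function(gene1, gene2) {
  stopifnot(length(gene1) == length(gene2))
  g1 <- .normalizeGeneName(as.character(gene1))
  g2 <- .normalizeGeneName(as.character(gene2))
  bad <- !nzchar(g1) | !nzchar(g2)
  if (any(bad))
    stop(sprintf(
      "empty gene name after normalization at position(s) %s",
      paste(which(bad), collapse = ", ")
    ))
  paste0(g1, "::", g2)
}

#' Split a canonical key into its per-side gene symbol lists
#'
#' Composite partners (comma-separated alternatives) expand to multiple
#' symbols on that side.
#'
#' @param key character vector of canonical keys.
#' @return list with components `genes5` and `genes3`, each a list of
#'   character vectors parallel to `key`.
#' @export
splitKey <- function(key) {
  sides <- strsplit(key, "::", fixed = TRUE)
  bad <- lengths(sides) != 2L
  if (any(bad))
    stop(sprintf("malformed key(s): %s", paste(key[bad], collapse = ", ")))
  list(
    genes5 = lapply(sides, function(s) strsplit(s[1], ",", fixed = TRUE)[[1]]),
    genes3 = lapply(sides, function(s) strsplit(s[2], ",", fixed = TRUE)[[1]])
  )
}

.parseBreakpoint <- function(bp, what, rows) {
  m <- regmatches(bp, regexpr("^(.*):([0-9]+)$", bp))
  ok <- grepl("^.+:[0-9]+$", bp)
  if (!all(ok))
    stop(sprintf(
      "unparseable %s '%s' at data row %d (expected 'chrom:pos')",
      what, bp[!ok][1], rows[!ok][1]
    ))
  chrom <- sub(":[0-9]+$", "", bp)
  pos <- as.integer(sub("^.*:", "", bp))
  list(chrom = chrom, pos = pos)
}

#' Read a fusion-call table in the Arriba TSV dialect
#'
#' Expects a tab-separated file whose header line begins with `#gene1`.
#' The required columns are `gene1`, `gene2`, `breakpoint1`, `breakpoint2`,
#' `confidence`, `split_reads1`, `split_reads2`, `discordant_mates`; any
#' further columns are carried along unchanged. Confidence strings are
#' matched case-insensitively and normalized to lower case. Breakpoints are
#' parsed from `"chrom:pos"` (1-based positions, chromosome names verbatim).
#'
#' @param path file path.
#' @param sample_id either a single sample id applied to all rows (per-sample
#'   Arriba output) or `"from-column"` to take ids from a `sample_id` column
#'   of a merged per-cohort file.
#' @param chromPrefixMap optional named character vector mapping chromosome
#'   names as found in the file to harmonized names.
#' @return data.frame with one row per call: `sample_id`, `gene1`, `gene2`,
#'   `breakpoint1`, `breakpoint2`, `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `confidence`, `split_reads1`, `split_reads2`, `discordant_mates`,
#'   optional `filters`/`type`, the canonical `key`, and any extra columns.
#'   The original column order is kept in `attr(, "source_columns")` so that
#'   [writeFusionTable()] round-trips the file.
#' @export
readFusionTable <- function(path, sample_id = "from-column",
                            chromPrefixMap = NULL) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#gene1"))
    stop(sprintf("'%s' does not look like an Arriba fusion table (header must begin with '#gene1')", path))
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path,
    header = FALSE, skip = 1L, sep = "\t", quote = "",
    comment.char = "", colClasses = "character",
    col.names = cols, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  names(df) <- cols
  miss <- setdiff(.REQUIRED_FUSION_COLS, cols)
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))

  if (identical(sample_id, "from-column")) {
    if (!"sample_id" %in% cols)
      stop("sample_id = \"from-column\" but the file has no 'sample_id' column")
  } else {
    stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
    df$sample_id <- rep(sample_id, nrow(df))
  }
  if (nrow(df) == 0L) {
    df$sample_id <- character(0)
    out <- .finalizeFusionTable(df, cols, chromPrefixMap)
    return(out)
  }
  if (any(!nzchar(df$sample_id)))
    stop(sprintf("empty sample_id at data row %d", which(!nzchar(df$sample_id))[1]))

  conf <- tolower(trimws(df$confidence))
  bad <- !conf %in% .CONFIDENCE_LEVELS
  if (any(bad))
    stop(sprintf(
      "unparseable confidence value '%s' at data row %d",
      df$confidence[bad][1], which(bad)[1]
    ))
  df$confidence <- conf

  for (cc in c("split_reads1", "split_reads2", "discordant_mates")) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (any(is.na(v)) || any(v < 0L))
      stop(sprintf(
        "column '%s' must hold non-negative integers (data row %d)",
        cc, which(is.na(v) | v < 0L)[1]
      ))
    df[[cc]] <- v
  }
  .finalizeFusionTable(df, cols, chromPrefixMap)
}

.finalizeFusionTable <- function(df, sourceCols, chromPrefixMap) {
  n <- nrow(df)
  if (n) {
    b1 <- .parseBreakpoint(df$breakpoint1, "breakpoint1", seq_len(n))
    b2 <- .parseBreakpoint(df$breakpoint2, "breakpoint2", seq_len(n))
    if (!is.null(chromPrefixMap)) {
      map <- function(x) ifelse(x %in% names(chromPrefixMap), chromPrefixMap[x], x)
      b1$chrom <- unname(map(b1$chrom))
      b2$chrom <- unname(map(b2$chrom))
    }
    df$chrom1 <- b1$chrom; df$pos1 <- b1$pos
    df$chrom2 <- b2$chrom; df$pos2 <- b2$pos
    df$key <- canonicalKey(df$gene1, df$gene2)
  } else {
    df$chrom1 <- character(0); df$pos1 <- integer(0)
    df$chrom2 <- character(0); df$pos2 <- integer(0)
    df$key <- character(0)
  }
  rownames(df) <- NULL
  attr(df, "source_columns") <- sourceCols
  df
}

#' Write a fusion-call table back to the Arriba TSV dialect
#'
#' Writes the columns that were present in the source file (recorded in
#' `attr(calls, "source_columns")`), restoring the `#gene1` header, so that
#' a valid file round-trips through [readFusionTable()].
#'
#' @param calls data.frame from [readFusionTable()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFusionTable <- function(calls, path) {
  cols <- attr(calls, "source_columns")
  if (is.null(cols))
    cols <- intersect(
      c("sample_id", .REQUIRED_FUSION_COLS, "filters", "type"),
      names(calls)
    )
  header <- paste0("#", paste(cols, collapse = "\t"))
  body <- do.call(paste, c(lapply(cols, function(cc) as.character(calls[[cc]])),
    sep = "\t"
  ))
  writeLines(c(header, if (nrow(calls)) body), path)
  invisible(path)
}

#' Read a clinical table
#'
#' CSV with header `sample_id,patient_id,time,event,ggg,tcc,specimen_age,score`
#' (`specimen_age` and `score` optional, empty fields become `NA`).
#' `time` is in months, `event` is 0/1, `ggg` is the Gleason Grading Group
#' (integer 1-5), `tcc` the tumor cell content in percent.
#'
#' @param path file path.
#' @param onePerPatient if `TRUE`, patients represented by multiple samples
#'   are reduced to their first available sample (first row in file order).
#' @return validated data.frame, one row per sample.
#' @export
readClinical <- function(path, onePerPatient = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("sample_id", "patient_id", "time", "event", "ggg", "tcc")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop(sprintf("clinical table misses column(s): %s", paste(miss, collapse = ", ")))
  if (!"specimen_age" %in% names(df)) df$specimen_age <- NA_real_
  if (!"score" %in% names(df)) df$score <- NA_real_

  if (anyDuplicated(df$sample_id))
    stop(sprintf(
      "duplicate sample_id: %s",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")
    ))
  if (onePerPatient) {
    keep <- !duplicated(df$patient_id)
    df <- df[keep, , drop = FALSE]
  }
  .checkRow <- function(ok, what) {
    if (any(!ok))
      stop(sprintf("%s (row %d, sample '%s')", what,
        which(!ok)[1], df$sample_id[which(!ok)[1]]))
  }
  df$time <- as.numeric(df$time)
  .checkRow(!is.na(df$time) & df$time >= 0, "time must be a non-negative number")
  .checkRow(df$event %in% c(0, 1), "event flag must be 0 or 1")
  df$event <- as.integer(df$event)
  gggKnown <- !is.na(df$ggg)
  .checkRow(!gggKnown | (df$ggg %in% 1:5), "ggg must be an integer in 1..5")
  df$ggg <- as.integer(df$ggg)
  tccKnown <- !is.na(df$tcc)
  .checkRow(!tccKnown | (df$tcc >= 0 & df$tcc <= 100), "tcc must lie in [0,100]")
  df$tcc <- as.numeric(df$tcc)
  df$specimen_age <- as.numeric(df$specimen_age)
  ageKnown <- !is.na(df$specimen_age)
  .checkRow(!ageKnown | df$specimen_age >= 0, "specimen_age must be non-negative")
  df$score <- as.numeric(df$score)
  rownames(df) <- NULL
  df
}

#' Read a known-fusion catalog
#'
#' Accepts either a plain list of one canonical fusion key per line, or a
#' CSV with a column named `fusion`. Keys are canonicalized on input.
#'
#' @param path file path.
#' @param sourceLabel provenance label stored on the catalog.
#' @return a [KnownFusionCatalog-class].
#' @export
readCatalog <- function(path, sourceLabel = basename(path)) {
  first <- readLines(path, n = 1L)
  if (grepl("(^|,)fusion(,|$)", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    entries <- df$fusion
  } else {
    entries <- readLines(path)
    entries <- trimws(entries)
    entries <- entries[nzchar(entries)]
  }
  knownFusionCatalog(entries, sourceLabel = sourceLabel)
}

#' Read a gene annotation table as a GRanges
#'
#' TSV with header `symbol,chrom,start,end,strand,gene_class,host_of,gene_sets`
#' (`host_of`, `gene_sets` semicolon-delimited; empty for none). Coordinates
#' are 1-based inclusive. Strand `unknown` maps to `*`.
#'
#' @param path file path.
#' @return a [GenomicRanges::GRanges] named by gene symbol with metadata
#'   columns `symbol`, `gene_class`, `host_of` (CharacterList) and
#'   `gene_sets` (CharacterList).
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.delim(path,
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = "character"
  )
  needed <- c("symbol", "chrom", "start", "end", "strand", "gene_class", "host_of", "gene_sets")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop(sprintf("gene annotation misses column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$symbol))
    stop(sprintf(
      "duplicate gene symbol(s): %s",
      paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", ")
    ))
  start <- as.integer(df$start); end <- as.integer(df$end)
  if (any(is.na(start) | is.na(end) | start > end))
    stop(sprintf("invalid coordinates for gene '%s'",
      df$symbol[which(is.na(start) | is.na(end) | start > end)[1]]))
  strand <- ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  splitSemis <- function(x) {
    IRanges::CharacterList(lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    }))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand
  )
  S4Vectors::mcols(gr)$symbol <- df$symbol
  S4Vectors::mcols(gr)$gene_class <- df$gene_class
  S4Vectors::mcols(gr)$host_of <- splitSemis(df$host_of)
  S4Vectors::mcols(gr)$gene_sets <- splitSemis(df$gene_sets)
  names(gr) <- df$symbol
  gr
}
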