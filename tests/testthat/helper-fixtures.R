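# Builders for small in-memory fixtures.

# One fusion-call row with sensible defaults.
callRow <- function(sample, g1, g2, conf = "high",
                    sr1 = 3L, sr2 = 2L, dm = 1L,
                    bp1 = "1:1000", bp2 = "2:2000") {
  n <- max(length(sample), length(g1), length(g2))
  g1 <- rep_len(g1, n)
  g2 <- rep_len(g2, n)
  data.frame(
    sample_id = sample, gene1 = g1, gene2 = g2,
    breakpoint1 = bp1, breakpoint2 = bp2,
    chrom1 = sub(":.*", "", bp1), pos1 = as.integer(sub(".*:", "", bp1)),
    chrom2 = sub(":.*", "", bp2), pos2 = as.integer(sub(".*:", "", bp2)),
    confidence = conf,
    split_reads1 = as.integer(sr1), split_reads2 = as.integer(sr2),
    discordant_mates = as.integer(dm),
    key = canonicalKey(g1, g2),
    stringsAsFactors = FALSE
  )
}

makeCalls <- function(...) {
  do.call(rbind, list(...))
}

# Write an Arriba-dialect file from raw fields.
writeArribaFile <- function(path, rows,
                            cols = c(
                              "gene1", "gene2", "breakpoint1", "breakpoint2",
                              "split_reads1", "split_reads2",
                              "discordant_mates", "confidence", "sample_id"
                            )) {
  header <- paste0("#", paste(cols, collapse = "\t"))
  body <- apply(rows[, cols, drop = FALSE], 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  path
}

# Gene annotation GRanges built in code.
makeAnnotation <- function(df) {
  path <- tempfile(fileext = ".tsv")
  if (!"strand" %in% names(df)) df$strand <- "+"
  if (!"gene_class" %in% names(df)) df$gene_class <- "protein_coding"
  if (!"host_of" %in% names(df)) df$host_of <- ""
  if (!"gene_sets" %in% names(df)) df$gene_sets <- ""
  write.table(df[, c("symbol", "chrom", "start", "end", "strand",
                     "gene_class", "host_of", "gene_sets")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  readGeneAnnotation(path)
}

# A call set with exact per-level distinct (sample, key) totals, used to
# reconstruct printed per-cohort summary numbers. Counts are spread evenly
# over the samples; keys are unique per (level, index).
callSetWithTotals <- function(name, nSamples, nHigh, nMedium, nLow,
                              role = "discovery", preservation = "fresh_frozen") {
  mk <- function(level, count) {
    if (count == 0) return(NULL)
    sample_idx <- rep_len(seq_len(nSamples), count)
    g1 <- sprintf("%s_G%05d", toupper(level), seq_len(count))
    callRow(
      sprintf("%s_S%03d", name, sample_idx), g1, "PARTNER",
      conf = level
    )
  }
  calls <- rbind(mk("high", nHigh), mk("medium", nMedium), mk("low", nLow))
  fusionCallSet(
    cohortConfig(name, role, preservation, nSamples = nSamples),
    calls
  )
}

overlapFixturePath <- function() {
  system.file("extdata", "three_cohort_overlap.tsv",
    package = "FusionBurden", mustWork = TRUE)
}

overlapFixture <- function() {
  read.delim(overlapFixturePath(), stringsAsFactors = FALSE, check.names = FALSE)
}
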