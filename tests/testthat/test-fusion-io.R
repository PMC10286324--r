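test_that("canonical keys strip caller distance annotations and preserve order", {
  expect_equal(canonicalKey("TMPRSS2", "ERG"), "TMPRSS2::ERG")
  expect_equal(
    canonicalKey("MBTPS2(33,120),LL0XNC01-39B3.1(20,917)", "SMS"),
    "MBTPS2,LL0XNC01-39B3.1::SMS"
  )
  expect_equal(canonicalKey("ERG", "ERG"), "ERG::ERG")
  # only digit/comma groups are stripped, other parentheses survive
  expect_equal(canonicalKey("GENE(AB)", "X"), "GENE(AB)::X")
  # vectorized
  expect_equal(
    canonicalKey(c("A(12)", "B"), c("C", "D(1,2)")),
    c("A::C", "B::D")
  )
  expect_error(canonicalKey("(123)", "ERG"), "empty gene name")
})

test_that("canonicalKey is idempotent and order-sensitive", {
  set.seed(42)
  syms <- c("TMPRSS2", "ERG(30,742),NCRNA00114(46,499)", "RP11-356O9.1",
            "MBTPS2(33,120)", "AC004921.2", "SNORD3A")
  for (i in 1:25) {
    g1 <- sample(syms, 1); g2 <- sample(setdiff(syms, g1), 1)
    key <- canonicalKey(g1, g2)
    parts <- strsplit(key, "::", fixed = TRUE)[[1]]
    expect_equal(canonicalKey(parts[1], parts[2]), key)
    expect_false(key == canonicalKey(g2, g1))
  }
})

test_that("splitKey expands composite partners", {
  s <- splitKey("MBTPS2,LL0XNC01-39B3.1::SMS")
  expect_equal(s$genes5[[1]], c("MBTPS2", "LL0XNC01-39B3.1"))
  expect_equal(s$genes3[[1]], "SMS")
  expect_error(splitKey("notakey"), "malformed")
})

test_that("Arriba-dialect tables parse, validate and round-trip", {
  rows <- data.frame(
    gene1 = c("TMPRSS2", "A(12),B"), gene2 = c("ERG", "C"),
    breakpoint1 = c("21:41498119", "X:1000"),
    breakpoint2 = c("21:38445621", "1:2000"),
    split_reads1 = c(3L, 0L), split_reads2 = c(2L, 1L),
    discordant_mates = c(1L, 0L),
    confidence = c("high", "low"),
    sample_id = c("S1", "S1"),
    stringsAsFactors = FALSE
  )
  path <- writeArribaFile(tempfile(), rows)
  calls <- readFusionTable(path)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$confidence, c("high", "low"))
  expect_equal(calls$chrom1, c("21", "X"))
  expect_equal(calls$pos1, c(41498119L, 1000L))
  expect_equal(calls$key, c("TMPRSS2::ERG", "A,B::C"))
  expect_equal(calls$split_reads1, c(3L, 0L))

  # round-trip is byte identical for a valid file
  out <- tempfile()
  writeFusionTable(calls, out)
  expect_identical(readLines(out), readLines(path))

  # fixed sample id overrides
  calls2 <- readFusionTable(path, sample_id = "SX")
  expect_equal(unique(calls2$sample_id), "SX")
})

test_that("fusion table edge cases: empty file, case variants, errors", {
  rows <- data.frame(
    gene1 = "A", gene2 = "B", breakpoint1 = "1:1", breakpoint2 = "1:2",
    split_reads1 = 1L, split_reads2 = 1L, discordant_mates = 0L,
    confidence = "HIGH", sample_id = "S1", stringsAsFactors = FALSE
  )
  path <- writeArribaFile(tempfile(), rows)
  expect_equal(readFusionTable(path)$confidence, "high")

  empty <- tempfile()
  writeLines(paste0("#", paste(names(rows), collapse = "\t")), empty)
  expect_equal(nrow(readFusionTable(empty)), 0L)

  rows$confidence <- "certain"
  expect_error(readFusionTable(writeArribaFile(tempfile(), rows)),
    "unparseable confidence value 'certain' at data row 1")

  rows$confidence <- "high"
  path3 <- writeArribaFile(tempfile(), rows,
    cols = setdiff(names(rows), "discordant_mates"))
  expect_error(readFusionTable(path3), "discordant_mates")

  bad <- tempfile()
  writeLines(c("gene1\tgene2", "A\tB"), bad)
  expect_error(readFusionTable(bad), "#gene1")
})

test_that("chromosome prefix mapping is applied when configured", {
  rows <- data.frame(
    gene1 = "A", gene2 = "B", breakpoint1 = "1:10", breakpoint2 = "MT:20",
    split_reads1 = 1L, split_reads2 = 0L, discordant_mates = 0L,
    confidence = "low", sample_id = "S1", stringsAsFactors = FALSE
  )
  calls <- readFusionTable(writeArribaFile(tempfile(), rows),
    chromPrefixMap = c("1" = "chr1", "MT" = "chrM"))
  expect_equal(calls$chrom1, "chr1")
  expect_equal(calls$chrom2, "chrM")
  # raw breakpoint strings untouched (reporting only)
  expect_equal(calls$breakpoint1, "1:10")
})

test_that("clinical tables validate and reduce to one sample per patient", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,patient_id,time,event,ggg,tcc,specimen_age,score",
    "S1,P1,24.0,1,3,70,6.5,0.2",
    "S2,P1,10.0,0,2,80,7.1,",
    "S3,P2,36.5,0,1,55,,"
  ), path)
  clin <- readClinical(path)
  expect_equal(nrow(clin), 3L)
  expect_equal(clin$time[1], 24.0)
  expect_true(is.na(clin$specimen_age[3]))

  reduced <- readClinical(path, onePerPatient = TRUE)
  expect_equal(reduced$sample_id, c("S1", "S3")) # first available kept

  writeLines(c(
    "sample_id,patient_id,time,event,ggg,tcc",
    "S1,P1,24.0,1,7,70"
  ), path)
  expect_error(readClinical(path), "ggg.*row 1")

  writeLines(c(
    "sample_id,patient_id,time,event,ggg,tcc",
    "S1,P1,24.0,2,3,70"
  ), path)
  expect_error(readClinical(path), "event")

  writeLines(c(
    "sample_id,patient_id,time,event,ggg,tcc",
    "S1,P1,24.0,1,3,70",
    "S1,P2,10.0,0,2,50"
  ), path)
  expect_error(readClinical(path), "duplicate sample_id")
})

test_that("catalogs read from plain lists and CSV, canonicalizing keys", {
  p1 <- tempfile()
  writeLines(c("TMPRSS2::ERG", "MBTPS2(33,120),LL0XNC01-39B3.1(20,917)::SMS"), p1)
  cat1 <- readCatalog(p1)
  expect_setequal(
    catalogEntries(cat1),
    c("TMPRSS2::ERG", "MBTPS2,LL0XNC01-39B3.1::SMS")
  )
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("fusion,source", "TMPRSS2::ERG,db", "SLC45A3::ELK4,db"), p2)
  expect_setequal(catalogEntries(readCatalog(p2)),
    c("TMPRSS2::ERG", "SLC45A3::ELK4"))
})

test_that("gene annotation loads as a validated GRanges", {
  ann <- exampleGeneAnnotation()
  expect_s4_class(ann, "GRanges")
  expect_true("TMPRSS2" %in% names(ann))
  expect_equal(
    S4Vectors::mcols(ann["TTC6"])$host_of[[1]], "SNORD127")
  expect_true("ETS_family" %in% S4Vectors::mcols(ann["ERG"])$gene_sets[[1]])
  expect_true(all(GenomicRanges::start(ann) <= GenomicRanges::end(ann)))

  expect_error(
    makeAnnotation(data.frame(
      symbol = c("A", "A"), chrom = "1", start = 1, end = 10
    )),
    "duplicate gene symbol"
  )
  expect_error(
    makeAnnotation(data.frame(symbol = "A", chrom = "1", start = 10, end = 1)),
    "invalid coordinates"
  )
})
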