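## Seeded generator for multi-cohort fusion-call tables and linked clinical
## outcomes with the statistical structure the analysis pipeline assumes:
## known fusions drawn by prevalence, negative-binomial background burden,
## per-call confidence whose distribution degrades with FFPE specimen age,
## duplicate calls exercising the dedup rule, spurious low-confidence calls,
## and Weibull survival whose hazard depends on dichotomized true burden and
## Gleason Grading Group.

#' Simulation configuration
#'
#' @slot seed global integer seed; per-cohort streams are derived from it
#'   deterministically.
#' @slot cohorts list of cohort specifications, see [simCohort()].
#' @slot catalogPrevalences named numeric: per-sample carrier probability of
#'   each known fusion key.
#' @slot ffpeAgeRange specimen-age range (years) for FFPE samples.
#' @slot degradationSlope probability mass shifted from high to low
#'   confidence per extra year of FFPE storage.
#' @slot spuriousRate rho: FFPE samples acquire Poisson(rho * age * lambda)
#'   spurious calls.
#' @slot spuriousConfidence probabilities over (high, medium, low) for
#'   spurious calls.
#' @slot duplicateRate probability that a true fusion is reported twice in
#'   a sample.
#' @slot readSupport list `mean`, `size` (negative-binomial law for total
#'   supporting reads) and `ffpeFactor` (multiplicative reduction for FFPE).
#' @slot survival list `shape`, `scale` (baseline Weibull, months), `beta1`
#'   (logHR of the high-burden group), `beta2` (logHR per GGG unit),
#'   `censoringMax` (uniform censoring window, months).
#' @slot gggProbs probabilities of Gleason Grading Groups 1-5.
#' @slot annotation gene annotation GRanges used as the background gene pool.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    seed = "integer",
    cohorts = "list",
    catalogPrevalences = "numeric",
    ffpeAgeRange = "numeric",
    degradationSlope = "numeric",
    spuriousRate = "numeric",
    spuriousConfidence = "numeric",
    duplicateRate = "numeric",
    readSupport = "list",
    survival = "list",
    gggProbs = "numeric",
    annotation = "ANY"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  probOK <- function(p) all(p >= 0 & p <= 1)
  if (!probOK(object@catalogPrevalences))
    msg <- c(msg, "catalog prevalences must lie in [0,1]")
  if (object@duplicateRate < 0 || object@duplicateRate > 1)
    msg <- c(msg, "duplicateRate must lie in [0,1]")
  if (object@spuriousRate < 0) msg <- c(msg, "spuriousRate must be >= 0")
  if (length(object@ffpeAgeRange) != 2L || diff(object@ffpeAgeRange) < 0)
    msg <- c(msg, "ffpeAgeRange must be c(min, max)")
  if (abs(sum(object@gggProbs) - 1) > 1e-8 || length(object@gggProbs) != 5L)
    msg <- c(msg, "gggProbs must be 5 probabilities summing to 1")
  if (abs(sum(object@spuriousConfidence) - 1) > 1e-8)
    msg <- c(msg, "spuriousConfidence must sum to 1")
  for (co in object@cohorts) {
    if (co$lambda <= 0) msg <- c(msg, sprintf("cohort '%s': lambda must be > 0", co$name))
    if (abs(sum(co$confidence) - 1) > 1e-8)
      msg <- c(msg, sprintf("cohort '%s': confidence probabilities must sum to 1", co$name))
    if (!probOK(co$confidence))
      msg <- c(msg, sprintf("cohort '%s': confidence probabilities must lie in [0,1]", co$name))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: seed=%d, %d cohort(s) [%s], %d catalog fusion(s)\n",
    object@seed, length(object@cohorts),
    paste(vapply(object@cohorts, `[[`, character(1), "name"), collapse = ", "),
    length(object@catalogPrevalences)
  ))
})

#' Cohort specification for the simulator
#'
#' @param name cohort name.
#' @param role `"discovery"`, `"confirmation"` or `"evaluation"`.
#' @param preservation `"fresh_frozen"` or `"FFPE"`.
#' @param library `"totalRNA"` or `"polyA"` (poly(A) cohorts draw no
#'   snoRNA/snRNA background partners, mirroring what the protocol can see).
#' @param nSamples number of samples.
#' @param lambda mean true (background) fusion burden per sample.
#' @param size negative-binomial dispersion of the background burden.
#' @param confidence baseline probabilities over (high, medium, low)
#'   confidence for true calls; for FFPE cohorts this is the distribution at
#'   the youngest specimen age.
#' @param endpointLabel survival endpoint label.
#' @return named list consumed by [simConfig()].
#' @export
simCohort <- function(name, role, preservation, library = "totalRNA",
                      nSamples, lambda, size = 2,
                      confidence = c(high = 0.25, medium = 0.3, low = 0.45),
                      endpointLabel = "BCR") {
  stopifnot(all(c("high", "medium", "low") %in% names(confidence)))
  list(
    name = name, role = role, preservation = preservation, library = library,
    nSamples = as.integer(nSamples), lambda = lambda, size = size,
    confidence = confidence[c("high", "medium", "low")],
    endpointLabel = endpointLabel
  )
}

#' Construct a SimConfig
#'
#' @param seed global integer seed.
#' @param cohorts list of [simCohort()] specifications.
#' @param catalogPrevalences named numeric of known-fusion carrier
#'   probabilities (default: TMPRSS2::ERG at 0.5, the approximate prevalence
#'   in prostate cancer of European descent, and SLC45A3::ELK4 at 0.1).
#' @param ffpeAgeRange,degradationSlope,spuriousRate,spuriousConfidence
#'   FFPE degradation model, see [SimConfig-class].
#' @param duplicateRate probability of a duplicate report per true fusion.
#' @param readSupport list `mean`, `size`, `ffpeFactor`.
#' @param survival list `shape`, `scale`, `beta1`, `beta2`, `censoringMax`.
#' @param gggProbs probabilities of GGG 1-5.
#' @param annotation gene annotation GRanges; defaults to the packaged
#'   synthetic annotation ([exampleGeneAnnotation()]).
#' @return a [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      cohorts,
                      catalogPrevalences = c("TMPRSS2::ERG" = 0.5, "SLC45A3::ELK4" = 0.1),
                      ffpeAgeRange = c(4.5, 11.1),
                      degradationSlope = 0.008,
                      spuriousRate = 1.6,
                      spuriousConfidence = c(high = 0, medium = 0.07, low = 0.93),
                      duplicateRate = 0.15,
                      readSupport = list(mean = 12, size = 1.5, ffpeFactor = 0.4),
                      survival = list(
                        shape = 1.2, scale = 1500,
                        beta1 = 0.7, beta2 = 0.65, censoringMax = 120
                      ),
                      gggProbs = c(0.25, 0.30, 0.20, 0.15, 0.10),
                      annotation = exampleGeneAnnotation()) {
  if (length(annotation) < 2L)
    stop("annotation must contain at least two genes")
  new("SimConfig",
    seed = as.integer(seed), cohorts = cohorts,
    catalogPrevalences = catalogPrevalences,
    ffpeAgeRange = as.numeric(ffpeAgeRange),
    degradationSlope = degradationSlope,
    spuriousRate = spuriousRate,
    spuriousConfidence = spuriousConfidence[c("high", "medium", "low")],
    duplicateRate = duplicateRate,
    readSupport = readSupport, survival = survival,
    gggProbs = gggProbs, annotation = annotation
  )
}

#' Packaged synthetic gene annotation
#'
#' A small synthetic gene table (plausible prostate-cancer fusion partners,
#' snoRNAs with host links, clone-derived identifiers, and filler genes with
#' synthetic coordinates) shipped with the package and used as the default
#' background gene pool of the simulator.
#'
#' @return GRanges, see [readGeneAnnotation()].
#' @export
exampleGeneAnnotation <- function() {
  readGeneAnnotation(system.file("extdata", "genes_synthetic.tsv",
    package = "FusionBurden", mustWork = TRUE
  ))
}

#' The study design emulated by default
#'
#' Returns a [SimConfig-class] describing four cohorts of the kind the
#' pipeline targets: two fresh-frozen discovery cohorts (one deeply
#' sequenced total-RNA cohort of 40 samples with a death-of-disease
#' endpoint, one poly(A) cohort of 332 samples), an FFPE biopsy confirmation
#' cohort of 176 samples whose call confidence degrades with specimen age,
#' and a fresh-frozen poly(A) evaluation cohort of 82 samples.
#'
#' @param seed global seed.
#' @param scale optional factor < 1 to shrink all cohort sizes
#'   proportionally (minimum 8 samples) for quick runs.
#' @return a [SimConfig-class].
#' @export
studyDesign <- function(seed = 1L, scale = 1) {
  shrink <- function(n) max(8L, as.integer(round(n * scale)))
  simConfig(
    seed = seed,
    cohorts = list(
      simCohort("FF_RP", "discovery", "fresh_frozen", "totalRNA",
        nSamples = shrink(40), lambda = 59, size = 2,
        confidence = c(high = 0.21, medium = 0.32, low = 0.47),
        endpointLabel = "DoD"
      ),
      simCohort("TCGA_PRAD", "discovery", "fresh_frozen", "polyA",
        nSamples = shrink(332), lambda = 39, size = 2,
        confidence = c(high = 0.25, medium = 0.17, low = 0.58),
        endpointLabel = "BCR"
      ),
      simCohort("FFPE_Bx", "confirmation", "FFPE", "totalRNA",
        nSamples = shrink(176), lambda = 45, size = 2,
        confidence = c(high = 0.062, medium = 0.20, low = 0.738),
        endpointLabel = "BCR"
      ),
      simCohort("DKFZ_RP", "evaluation", "fresh_frozen", "polyA",
        nSamples = shrink(82), lambda = 26, size = 2,
        confidence = c(high = 0.33, medium = 0.20, low = 0.47),
        endpointLabel = "BCR"
      )
    )
  )
}

.cohortSeed <- function(config, cohortName) {
  idx <- match(cohortName, vapply(config@cohorts, `[[`, character(1), "name"))
  if (is.na(idx)) stop(sprintf("no cohort named '%s' in the configuration", cohortName))
  withr_seed <- config@seed
  set.seed(withr_seed)
  draws <- sample.int(2147483646L, length(config@cohorts))
  draws[idx]
}

.genePool <- function(annotation, library) {
  cls <- S4Vectors::mcols(annotation)$gene_class
  syms <- names(annotation)
  if (library == "polyA") syms <- syms[!cls %in% c("snoRNA", "snRNA")]
  syms
}

## plain-vector lookup tables for fast vectorized draws
.annLookup <- function(annotation) {
  list(
    chrom = stats::setNames(as.character(GenomicRanges::seqnames(annotation)), names(annotation)),
    start = stats::setNames(GenomicRanges::start(annotation), names(annotation)),
    width = stats::setNames(GenomicRanges::width(annotation), names(annotation))
  )
}

.drawBreakpoints <- function(syms, lut) {
  first <- vapply(strsplit(syms, ",", fixed = TRUE), `[[`, character(1), 1L)
  known <- first %in% names(lut$chrom)
  chrom <- ifelse(known, lut$chrom[first], "chrU")
  width <- ifelse(known, lut$width[first], 1000000L)
  start <- ifelse(known, lut$start[first], 1L)
  pos <- start + floor(stats::runif(length(syms)) * width)
  sprintf("%s:%d", chrom, as.integer(pos))
}

## random ordered gene pairs with distinct partners
.drawGenePairs <- function(pool, k) {
  g1 <- sample(pool, k, replace = TRUE)
  g2 <- sample(pool, k, replace = TRUE)
  same <- g1 == g2
  while (any(same)) {
    g2[same] <- sample(pool, sum(same), replace = TRUE)
    same <- g1 == g2
  }
  cbind(g1, g2)
}

.ffpeConfidence <- function(base, age, ageMin, slope) {
  shift <- min(slope * max(0, age - ageMin), base[["high"]] - 0.002)
  c(
    high = base[["high"]] - shift,
    medium = base[["medium"]],
    low = base[["low"]] + shift
  )
}

#' Simulate one cohort
#'
#' Per sample: known fusions are drawn by prevalence; background fusions are
#' random ordered gene pairs with a negative-binomial count; each true
#' fusion is emitted once plus a duplicate with probability `duplicateRate`
#' (independent confidence and read-support draws, exercising the dedup
#' rule); FFPE samples get a uniform specimen age, degraded confidence
#' probabilities and Poisson(rho * age * lambda) spurious calls; supporting
#' reads follow the configured negative-binomial law (reduced for FFPE) and
#' are split into split reads and discordant mates; survival times follow a
#' Weibull hazard multiplied by exp(beta1 * [true burden >= cohort median] +
#' beta2 * GGG) with independent uniform censoring.
#'
#' @param config a [SimConfig-class].
#' @param cohortName which cohort to simulate.
#' @return list with `calls` (Arriba-dialect data.frame), `clinical`,
#'   `truth` (per-sample true burden, true group, carrier flags; the true
#'   betas and the burden median are attached as attributes), and `cohort`
#'   (a [CohortConfig-class]).
#' @export
simulateCohort <- function(config, cohortName) {
  co <- config@cohorts[[match(
    cohortName,
    vapply(config@cohorts, `[[`, character(1), "name")
  )]]
  if (is.null(co)) stop(sprintf("unknown cohort '%s'", cohortName))
  set.seed(.cohortSeed(config, cohortName))
  ann <- config@annotation
  lut <- .annLookup(ann)
  pool <- .genePool(ann, co$library)
  isFFPE <- co$preservation == "FFPE"
  n <- co$nSamples
  sampleIds <- sprintf("%s_S%03d", co$name, seq_len(n))
  catalogKeys <- names(config@catalogPrevalences)

  supportDraw <- function(k, factor = 1) {
    tot <- stats::rnbinom(k, mu = config@readSupport$mean * factor,
      size = config@readSupport$size) + 1L
    # multinomial split (0.4, 0.4, 0.2) drawn sequentially
    s1 <- stats::rbinom(k, tot, 0.4)
    s2 <- stats::rbinom(k, tot - s1, 2 / 3)
    cbind(s1, s2, tot - s1 - s2)
  }

  callRows <- vector("list", n)
  truthRows <- vector("list", n)
  ages <- if (isFFPE) stats::runif(n, config@ffpeAgeRange[1], config@ffpeAgeRange[2]) else rep(NA_real_, n)

  for (i in seq_len(n)) {
    carriers <- stats::runif(length(catalogKeys)) < config@catalogPrevalences
    trueKeys <- catalogKeys[carriers]
    nBg <- stats::rnbinom(1, mu = co$lambda, size = co$size)
    if (nBg > 0) {
      gp <- .drawGenePairs(pool, nBg)
      trueKeys <- unique(c(trueKeys, canonicalKey(gp[, 1], gp[, 2])))
    }
    confProbs <- if (isFFPE) {
      .ffpeConfidence(co$confidence, ages[i], config@ffpeAgeRange[1],
        config@degradationSlope)
    } else {
      co$confidence
    }
    emitted <- if (length(trueKeys)) {
      reps <- 1L + stats::rbinom(length(trueKeys), 1L, config@duplicateRate)
      rep(trueKeys, reps)
    } else {
      character(0)
    }
    nSpur <- if (isFFPE && config@spuriousRate > 0) {
      stats::rpois(1, config@spuriousRate * ages[i] * co$lambda)
    } else {
      0L
    }
    spurKeys <- if (nSpur > 0) {
      sp <- .drawGenePairs(pool, nSpur)
      canonicalKey(sp[, 1], sp[, 2])
    } else {
      character(0)
    }
    allKeys <- c(emitted, spurKeys)
    if (length(allKeys)) {
      conf <- c(
        sample(.CONFIDENCE_LEVELS[3:1], length(emitted), replace = TRUE,
          prob = confProbs[c("high", "medium", "low")]),
        sample(.CONFIDENCE_LEVELS[3:1], length(spurKeys), replace = TRUE,
          prob = config@spuriousConfidence)
      )
      supp <- supportDraw(length(allKeys),
        factor = if (isFFPE) config@readSupport$ffpeFactor else 1)
      keyParts <- strsplit(allKeys, "::", fixed = TRUE)
      g5 <- vapply(keyParts, `[[`, character(1), 1L)
      g3 <- vapply(keyParts, `[[`, character(1), 2L)
      bp1 <- .drawBreakpoints(g5, lut)
      bp2 <- .drawBreakpoints(g3, lut)
      callRows[[i]] <- data.frame(
        gene1 = g5,
        gene2 = g3,
        breakpoint1 = bp1, breakpoint2 = bp2,
        split_reads1 = supp[, 1], split_reads2 = supp[, 2],
        discordant_mates = supp[, 3],
        confidence = conf,
        filters = ".", type = ifelse(seq_along(allKeys) > length(emitted), "spurious", "."),
        sample_id = sampleIds[i],
        stringsAsFactors = FALSE
      )
    }
    truthRow <- data.frame(
      sample_id = sampleIds[i],
      true_burden = length(trueKeys),
      specimen_age = ages[i],
      stringsAsFactors = FALSE
    )
    for (k in seq_along(catalogKeys)) truthRow[[catalogKeys[k]]] <- carriers[k]
    truthRows[[i]] <- truthRow
  }

  calls <- do.call(rbind, callRows[!vapply(callRows, is.null, logical(1))])
  if (is.null(calls)) {
    calls <- data.frame(
      gene1 = character(0), gene2 = character(0),
      breakpoint1 = character(0), breakpoint2 = character(0),
      split_reads1 = integer(0), split_reads2 = integer(0),
      discordant_mates = integer(0), confidence = character(0),
      filters = character(0), type = character(0), sample_id = character(0),
      stringsAsFactors = FALSE
    )
  }
  rownames(calls) <- NULL
  srcCols <- c(
    "gene1", "gene2", "breakpoint1", "breakpoint2", "split_reads1",
    "split_reads2", "discordant_mates", "confidence", "filters", "type",
    "sample_id"
  )
  calls <- .finalizeFusionTable(calls, srcCols, NULL)

  truth <- do.call(rbind, truthRows)
  medTrue <- stats::median(truth$true_burden)
  truth$true_group <- as.integer(truth$true_burden >= medTrue)

  sv <- config@survival
  ggg <- sample(1:5, n, replace = TRUE, prob = config@gggProbs)
  lp <- sv$beta1 * truth$true_group + sv$beta2 * ggg
  u <- stats::runif(n)
  tEvent <- sv$scale * (-log(u) / exp(lp))^(1 / sv$shape)
  cens <- stats::runif(n, 0, sv$censoringMax)
  clinical <- data.frame(
    sample_id = sampleIds,
    patient_id = sampleIds,
    time = pmin(tEvent, cens),
    event = as.integer(tEvent <= cens),
    ggg = ggg,
    tcc = round(stats::runif(n, if (isFFPE) 5 else 50, 100)),
    specimen_age = ages,
    score = lp + stats::rnorm(n, sd = 1),
    stringsAsFactors = FALSE
  )
  attr(truth, "beta1") <- sv$beta1
  attr(truth, "beta2") <- sv$beta2
  attr(truth, "median_true_burden") <- medTrue

  list(
    calls = calls, clinical = clinical, truth = truth,
    cohort = cohortConfig(co$name, co$role, co$preservation, co$library,
      co$endpointLabel, n)
  )
}

#' Simulate every cohort of a configuration
#'
#' @param config a [SimConfig-class].
#' @return named list of [simulateCohort()] results.
#' @export
simulateStudy <- function(config) {
  nms <- vapply(config@cohorts, `[[`, character(1), "name")
  stats::setNames(lapply(nms, function(nm) simulateCohort(config, nm)), nms)
}

#' Write simulated cohort files to disk
#'
#' Writes the Arriba-dialect calls file, the clinical CSV and the truth TSV
#' for each cohort, plus a manifest JSON.
#'
#' @param sims result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @return invisible list of written paths.
#' @export
writeSimOutput <- function(sims, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- lapply(names(sims), function(nm) {
    p <- list(
      calls = file.path(dir, paste0(nm, ".fusions.tsv")),
      clinical = file.path(dir, paste0(nm, ".clinical.csv")),
      truth = file.path(dir, paste0(nm, ".truth.tsv"))
    )
    writeFusionTable(sims[[nm]]$calls, p$calls)
    utils::write.csv(sims[[nm]]$clinical, p$clinical, row.names = FALSE)
    utils::write.table(sims[[nm]]$truth, p$truth,
      sep = "\t", row.names = FALSE, quote = FALSE)
    p
  })
  names(paths) <- names(sims)
  manifest <- list(
    seed = seed, cohorts = names(sims),
    files = lapply(paths, function(p) lapply(p, basename))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Recovery metrics for a simulated cohort
#'
#' Scores how well the pipeline recovered the simulated truth: exactness of
#' the deduplicated burden (estimated burden equals true burden when
#' duplicates but no spurious calls are present), rank correlation of
#' estimated vs. true burden, and, when a Cox result is supplied, the error
#' and CI coverage of the burden-group log hazard ratio.
#'
#' @param sim result of [simulateCohort()].
#' @param burdens result of [perSampleBurden()] on the pipeline's call set.
#' @param coxResult optional result of [coxFit()] whose first coefficient is
#'   the burden-group effect.
#' @return list of metrics.
#' @export
recoveryReport <- function(sim, burdens, coxResult = NULL) {
  bt <- burdens$burden
  idx <- match(sim$truth$sample_id, bt$sample_id)
  est <- bt$burden[idx]
  est[is.na(est)] <- 0L
  truth <- sim$truth$true_burden
  out <- list(
    n = length(truth),
    dedup_exact = all(est == truth),
    frac_exact = mean(est == truth),
    burden_rank_correlation = if (stats::sd(truth) > 0 && stats::sd(est) > 0) {
      stats::cor(est, truth, method = "spearman")
    } else {
      NA_real_
    }
  )
  if (!is.null(coxResult) && isTRUE(coxResult$converged)) {
    b1 <- attr(sim$truth, "beta1")
    co <- coxResult$coefficients[1, ]
    out$beta1_true <- b1
    out$beta1_hat <- co$logHR
    out$beta1_error <- co$logHR - b1
    out$ci_covers_beta1 <- co$ci_low <= b1 && b1 <= co$ci_high
  }
  out
}
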