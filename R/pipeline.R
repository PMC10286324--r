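## Staged orchestration of the analysis: summarize -> crosscohort ->
## annotate -> prognosis, driven by a YAML or list configuration, with a
## run manifest (config snapshot, input checksums, stage records, seed).

#' Build cohort fusion sets from a published detection-status table
#'
#' Encodes a table of fusions with per-cohort 0/1 detection flags (such as a
#' printed cross-cohort overlap table) as [CohortFusionSet-class] objects so
#' that [overlapAndRank()] and [novelCandidates()] can be run on it. Each
#' cohort's flagged keys become its high-confidence set; for confirmation
#' cohorts they also form the combined set. Keys are canonicalized from the
#' `gene1`/`gene2` columns.
#'
#' @param df data.frame with columns `gene1`, `gene2` and one 0/1 column per
#'   cohort.
#' @param roles named character vector mapping cohort column names to roles.
#' @return list of [CohortFusionSet-class] objects.
#' @export
fusionSetsFromStatusTable <- function(df, roles) {
  keys <- canonicalKey(df$gene1, df$gene2)
  lapply(names(roles), function(nm) {
    if (!nm %in% names(df)) stop(sprintf("no column '%s' in the table", nm))
    flagged <- keys[df[[nm]] == 1]
    new("CohortFusionSet",
      name = nm, role = unname(roles[nm]),
      keysByLevel = list(high = flagged, medium = character(0), low = character(0)),
      combinedKeys = if (roles[nm] == "confirmation") flagged else character(0)
    )
  })
}

.pipelineStageNames <- c("summarize", "crosscohort", "annotate", "prognosis")

.loadPipelineCohorts <- function(config) {
  lapply(config$cohorts, function(cc) {
    calls <- readFusionTable(cc$calls,
      sample_id = if (is.null(cc$sample_id)) "from-column" else cc$sample_id
    )
    clinical <- if (!is.null(cc$clinical)) {
      readClinical(cc$clinical,
        onePerPatient = isTRUE(cc$one_per_patient)
      )
    }
    nS <- if (!is.null(clinical)) nrow(clinical) else length(unique(calls$sample_id))
    list(
      callSet = fusionCallSet(
        cohortConfig(cc$name, cc$role, cc$preservation,
          if (is.null(cc$library)) "totalRNA" else cc$library,
          if (is.null(cc$endpoint)) "BCR" else cc$endpoint, nS
        ),
        calls
      ),
      clinical = clinical
    )
  })
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (summarize, crosscohort,
#' annotate, prognosis), writing each stage's outputs before the next
#' starts, and returns a run manifest. The configuration is either a YAML
#' file path or an equivalent nested list:
#'
#' \preformatted{
#' outdir: runs/demo
#' seed: 1
#' min_cohorts: 2
#' confidence_scope: high_only   # high_only | combined | all
#' ties: breslow                 # breslow | efron
#' stages: [summarize, crosscohort, annotate, prognosis]
#' catalog: known_fusions.txt
#' annotation: genes.tsv
#' cohorts:
#'   - name: FF_RP
#'     role: discovery
#'     preservation: fresh_frozen
#'     library: totalRNA
#'     endpoint: DoD
#'     calls: FF_RP.fusions.tsv
#'     clinical: FF_RP.clinical.csv
#' }
#'
#' @param config YAML file path or list.
#' @return the run manifest (invisibly also written to
#'   `outdir/manifest.json`): config snapshot, input checksums, per-stage
#'   records with output paths, seed.
#' @export
runPipeline <- function(config) {
  configPath <- NULL
  if (is.character(config)) {
    configPath <- config
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$cohorts) || !length(config$cohorts))
    stop("configuration names no cohorts")
  stages <- if (is.null(config$stages)) .pipelineStageNames else config$stages
  bad <- setdiff(stages, .pipelineStageNames)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  outdir <- if (is.null(config$outdir)) "." else config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  minCohorts <- if (is.null(config$min_cohorts)) 2L else as.integer(config$min_cohorts)
  scope <- if (is.null(config$confidence_scope)) "high_only" else config$confidence_scope
  ties <- if (is.null(config$ties)) "breslow" else config$ties

  inputs <- unlist(lapply(config$cohorts, function(cc) c(cc$calls, cc$clinical)))
  inputs <- c(inputs, config$catalog, config$annotation)
  checksums <- tools::md5sum(inputs[file.exists(inputs)])

  manifest <- list(
    config = config, config_path = configPath, seed = seed,
    input_checksums = as.list(checksums), stages = list()
  )
  runStage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- res
  }

  loaded <- .loadPipelineCohorts(config)
  callSets <- lapply(loaded, `[[`, "callSet")
  names(callSets) <- vapply(callSets, cohortName, character(1))
  catalog <- if (!is.null(config$catalog)) readCatalog(config$catalog)
  annotation <- if (!is.null(config$annotation)) readGeneAnnotation(config$annotation)

  candidateSets <- NULL

  if ("summarize" %in% stages) {
    runStage("summarize", function() {
      outs <- list()
      for (nm in names(callSets)) {
        smry <- summarizeCohort(callSets[[nm]])
        p <- file.path(outdir, paste0(nm, ".summary.tsv"))
        utils::write.table(cbind(level = rownames(smry), smry), p,
          sep = "\t", row.names = FALSE, quote = FALSE)
        b <- perSampleBurden(callSets[[nm]],
          scope = if (scope == "combined") "all" else scope,
          clinical = loaded[[match(nm, names(callSets))]]$clinical
        )
        pb <- file.path(outdir, paste0(nm, ".burden.tsv"))
        utils::write.table(b$burden, pb, sep = "\t", row.names = FALSE, quote = FALSE)
        outs[[nm]] <- list(
          summary = p, burden = pb,
          n_raw_calls = nrow(fusionCalls(callSets[[nm]])),
          n_analysis_calls = nrow(analysisCalls(callSets[[nm]])),
          median_burden = b$median_burden
        )
      }
      outs
    })
  }

  if ("crosscohort" %in% stages) {
    runStage("crosscohort", function() {
      if (is.null(catalog)) stop("crosscohort stage requires a catalog")
      candidateSets <<- buildCandidateSets(callSets)
      ov <- overlapAndRank(candidateSets, catalog, minCohorts = minCohorts)
      p <- file.path(outdir, "overlap.tsv")
      utils::write.table(ov, p, sep = "\t", row.names = FALSE, quote = FALSE)
      novel <- novelCandidates(ov, requireAllCohorts = TRUE)
      pj <- file.path(outdir, "novel_candidates.json")
      jsonlite::write_json(novel, pj)
      list(
        overlap = p, novel = pj, n_rows = nrow(ov),
        n_all_cohorts = sum(ov$n_cohorts == length(candidateSets)),
        n_novel_all_cohorts = length(novel)
      )
    })
  }

  if ("annotate" %in% stages) {
    runStage("annotate", function() {
      if (is.null(annotation)) stop("annotate stage requires a gene annotation")
      keys <- unique(unlist(lapply(callSets, function(cs) analysisCalls(cs)$key)))
      sno <- findSnoFusions(keys, annotation)
      rt <- suppressWarnings(readthroughCandidates(keys, annotation))
      tags <- vapply(keys, function(k) {
        sides <- splitKey(k)
        paste(sort(unique(c(
          classifyPartner(paste(sides$genes5[[1]], collapse = ","), annotation),
          classifyPartner(paste(sides$genes3[[1]], collapse = ","), annotation)
        ))), collapse = ";")
      }, character(1))
      ann <- data.frame(
        key = keys, tags = unname(tags),
        known = if (!is.null(catalog)) keys %in% catalogEntries(catalog) else NA,
        readthrough = rt$readthrough_candidate[match(keys, rt$key)],
        stringsAsFactors = FALSE
      )
      p <- file.path(outdir, "annotated_fusions.tsv")
      utils::write.table(ann, p, sep = "\t", row.names = FALSE, quote = FALSE)
      prom5 <- promiscuity(callSets, "5prime")
      prom3 <- promiscuity(callSets, "3prime")
      p5 <- file.path(outdir, "promiscuity_5prime.tsv")
      p3 <- file.path(outdir, "promiscuity_3prime.tsv")
      utils::write.table(prom5, p5, sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(prom3, p3, sep = "\t", row.names = FALSE, quote = FALSE)
      list(
        annotated = p, promiscuity_5prime = p5, promiscuity_3prime = p3,
        n_keys = length(keys), n_sno_fusions = nrow(sno)
      )
    })
  }

  if ("prognosis" %in% stages) {
    runStage("prognosis", function() {
      outs <- list()
      for (j in seq_along(callSets)) {
        nm <- names(callSets)[j]
        clinical <- loaded[[j]]$clinical
        if (is.null(clinical)) next
        cs <- callSets[[j]]
        ck <- NULL
        useScope <- scope
        if (scope == "combined") {
          if (cohortRole(cs) == "confirmation") {
            if (is.null(candidateSets)) candidateSets <- buildCandidateSets(callSets)
            ck <- combinedKeys(candidateSets[[j]])
          } else {
            useScope <- "high_only"
          }
        }
        b <- perSampleBurden(cs, scope = useScope, clinical = clinical, combinedKeys = ck)
        groups <- assignGroups(burdens = b, spec = groupingSpec("burden_median"))
        grp <- groups[clinical$sample_id]
        res <- list(cohort = nm, median_burden = b$median_burden,
          n = nrow(clinical), events = sum(clinical$event))
        if (length(unique(grp)) >= 2L && sum(clinical$event) >= 2L) {
          lr <- logRankTest(clinical$time, clinical$event, grp)
          cox <- coxFit(clinical$time, clinical$event,
            data.frame(burden_group = grp, ggg = clinical$ggg), ties = ties)
          res$logrank <- lr
          res$cox <- cox[c("coefficients", "converged", "n", "n_events")]
          for (g in c(0, 1)) {
            sel <- grp == g
            km <- kmFit(clinical$time[sel], clinical$event[sel])
            pk <- file.path(outdir, sprintf("%s.km_group%d.tsv", nm, g))
            utils::write.table(km$curve, pk, sep = "\t", row.names = FALSE, quote = FALSE)
          }
        } else {
          res$note <- "degenerate grouping or too few events; survival tests skipped"
        }
        outs[[nm]] <- res
      }
      pj <- file.path(outdir, "prognosis.json")
      jsonlite::write_json(outs, pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      list(results = pj, cohorts = names(outs))
    })
  }

  manifest$outputs <- outdir
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  manifest
}
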