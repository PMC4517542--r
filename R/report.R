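## Pipeline driver and report bundle: qc -> merge -> consequence -> UV
## -> summarize -> rank -> tests, with per-stage counts logged to
## standard error so the conservation invariants are visible in every
## run.

.logStage <- function(...) message(sprintf(...))

#' Annotate merged events
#'
#' Adds consequence, UV class and epigenetic category columns to a
#' merged event table.
#'
#' @param events event data.frame from [mergeAdjacentSnvs()].
#' @param models named list of [TranscriptModel].
#' @param registry an [EpigeneticRegistry].
#' @param mode UV classification mode, `"literal"` or `"pyrimidine"`.
#' @return `events` with columns consequence, uv_class,
#'   epigenetic_category added.
#' @export
annotateEvents <- function(events, models, registry,
                           mode = c("literal", "pyrimidine")) {
  mode <- match.arg(mode)
  events$consequence <- classifyConsequence(events, models)
  events$uv_class <- classifyUv(events$ref, events$alt,
                                consequence = events$consequence,
                                mode = mode)
  events$epigenetic_category <- registryCategory(registry, events$gene)
  events
}

#' Run the full cohort analysis
#'
#' QC-filters the variant table, merges adjacent SNVs into dinucleotide
#' events, classifies consequences and UV signatures, restricts to
#' non-silent events, tallies the cohort, ranks genes, and computes the
#' comparative statistics: the two-proportion z test on the epigenetic
#' share of the top-N genes versus the panel, and the two-sample t test
#' on per-gene UVB counts in epigenetic versus non-epigenetic genes.
#'
#' @param variants variant data.frame (see [readMutationTable()]).
#' @param models named list of [TranscriptModel].
#' @param registry an [EpigeneticRegistry].
#' @param panel a [PanelDefinition].
#' @param nSamples number of samples in the cohort; defaults to the
#'   number of distinct sample ids in `variants`.
#' @param annotations,sampleCoverage,qcConfig passed to [applyQc()].
#' @param mode UV classification mode (`"literal"` or `"pyrimidine"`).
#' @param denominatorMode per-gene UVB denominator (see
#'   [uvbPerGeneDistribution()]).
#' @param topN size of the gene ranking (default 40).
#' @param welch use the Welch t form (default FALSE, pooled Student).
#' @return list: summary ([CohortSummary]), ranking, burden, uvSpectrum
#'   (counts with both denominators: all events and UVB events),
#'   uvbDistributions, zTest and tTest ([TestResult]), events, rejects,
#'   removed, params.
#' @export
analyzeCohort <- function(variants, models, registry, panel,
                          nSamples = NULL, annotations = NULL,
                          sampleCoverage = NULL, qcConfig = QcConfig(),
                          mode = c("literal", "pyrimidine"),
                          denominatorMode = c("mutated_genes",
                                              "all_panel_genes"),
                          topN = 40L, welch = FALSE) {
  mode <- match.arg(mode)
  denominatorMode <- match.arg(denominatorMode)
  if (is.null(nSamples)) nSamples <- length(unique(variants$sample_id))

  qc <- applyQc(variants, annotations = annotations,
                sampleCoverage = sampleCoverage, cfg = qcConfig)
  .logStage("qc: %d read, %d kept, %d removed", nrow(variants),
            nrow(qc$variants), nrow(qc$removed))
  if (!nrow(qc$variants)) stop("no events after QC")

  events <- mergeAdjacentSnvs(qc$variants)
  .logStage("merge: %d variants -> %d events", nrow(qc$variants),
            nrow(events))
  events <- annotateEvents(events, models, registry, mode = mode)

  nonsilent <- events[events$consequence %in% NON_SILENT_CLASSES, ,
                      drop = FALSE]
  .logStage("non-silent: %d of %d events", nrow(nonsilent), nrow(events))
  if (!nrow(nonsilent)) stop("no events after QC")

  summary <- summarizeCohort(nonsilent, registry, panel, nSamples)
  ranking <- rankGenes(summary, topN)
  burden <- epigeneticBurden(summary)

  nTop <- nrow(ranking)
  nEpiPanel <- length(intersect(panelGenes(panel),
                                registryGenes(registry)))
  zTest <- twoProportionZ(sum(ranking$isEpigenetic), nTop, nEpiPanel,
                          length(panel))

  uvCounts <- summary@totals$byUv
  nEv <- summary@totals$nEvents
  nUvb <- summary@totals$nUvbEvents
  uvSpectrum <- list(
    counts = as.list(uvCounts),
    pctOfAllEvents = lapply(as.list(uvCounts), function(x)
      pctHalfUp(x, nEv)),
    pctOfUvbEvents = lapply(as.list(uvCounts[UVB_CLASSES]), function(x)
      if (nUvb > 0) pctHalfUp(x, nUvb) else NA_real_),
    uvbFraction = uvbFraction(nonsilent$uv_class))

  dEpi <- uvbPerGeneDistribution(summary, "epigenetic", denominatorMode)
  dNon <- uvbPerGeneDistribution(summary, "non_epigenetic",
                                 denominatorMode)
  tTest <- twoSampleT(dEpi$values, dNon$values, welch = welch)

  list(summary = summary, ranking = ranking, burden = burden,
       uvSpectrum = uvSpectrum,
       uvbDistributions = list(epigenetic = dEpi, non_epigenetic = dNon),
       zTest = zTest, tTest = tTest, events = nonsilent,
       allEvents = events, rejects = attr(variants, "rejects"),
       removed = qc$removed,
       params = list(mode = mode, denominatorMode = denominatorMode,
                     topN = topN, welch = welch, nSamples = nSamples))
}

.testResultList <- function(tr) {
  list(method = tr@method, statistic = tr@statistic, df = tr@df,
       p_two_sided = tr@pValue, estimate = tr@estimate,
       ci = c(tr@ciLow, tr@ciHigh), computable = tr@computable,
       inputs = tr@inputs)
}

#' Serialize an analysis to a JSON-ready list
#'
#' Flattens the [analyzeCohort()] result into plain lists/vectors so
#' that every number in the text report is traceable to a field of the
#' JSON summary.
#'
#' @param report result of [analyzeCohort()].
#' @return nested list.
#' @export
summaryAsList <- function(report) {
  s <- report$summary
  tot <- s@totals
  list(
    n_samples = s@nSamples,
    n_events = tot$nEvents,
    n_genes_mutated = s@nGenesMutated,
    n_panel_genes = length(s@panelGenes),
    pct_genes_mutated = pctHalfUp(s@nGenesMutated, length(s@panelGenes)),
    per_sample = as.list(s@perSampleStats),
    by_consequence = as.list(tot$byConsequence),
    pct_by_consequence = lapply(as.list(tot$byConsequence), function(x)
      pctHalfUp(x, tot$nEvents)),
    by_epigenetic_category = as.list(tot$byEpigeneticCategory),
    epigenetic = list(
      n_events = tot$nEpigeneticEvents,
      pct_of_events = pctHalfUp(tot$nEpigeneticEvents, tot$nEvents),
      burden = report$burden),
    uv = c(report$uvSpectrum,
           list(pct_uvb_of_events = pctHalfUp(tot$nUvbEvents,
                                              tot$nEvents))),
    uvb_per_gene = lapply(report$uvbDistributions, function(d)
      d[c("mean", "median", "mode", "sd", "n")]),
    top_genes = report$ranking,
    tests = list(top_gene_epigenetic_enrichment_z =
                   .testResultList(report$zTest),
                 uvb_per_gene_t = .testResultList(report$tTest)),
    params = report$params)
}

#' Write the report bundle
#'
#' Writes `summary.json`, `events.tsv`, `removed.tsv` and a
#' human-readable `report.txt` mirroring the cohort-results structure
#' (mutation-type table, top-N table, epigenetic burden, UV spectrum,
#' group comparison).  Output is byte-identical across runs on the same
#' input.
#'
#' @param report result of [analyzeCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReportBundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  js <- summaryAsList(report)
  jsonlite::write_json(js, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write.table(report$events, p("events.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(report$removed, p("removed.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")

  con <- file(p("report.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  s <- report$summary; tot <- s@totals
  w("Cohort mutation report")
  w("======================")
  w("%d non-silent mutations in %d of %d genes across %d samples",
    tot$nEvents, s@nGenesMutated, length(s@panelGenes), s@nSamples)
  w("mean %.1f / median %.1f / sd %.1f mutations per sample",
    s@perSampleStats[["mean"]], s@perSampleStats[["median"]],
    s@perSampleStats[["sd"]])
  w("")
  w("Mutation types:")
  for (cl in names(js$by_consequence))
    if (js$by_consequence[[cl]] > 0)
      w("  %-18s %4d (%s%%)", cl, js$by_consequence[[cl]],
        js$pct_by_consequence[[cl]])
  w("")
  w("Top %d genes (patients mutated, total mutations, epigenetic):",
    nrow(report$ranking))
  for (i in seq_len(nrow(report$ranking))) {
    r <- report$ranking[i, ]
    w("  %-10s %3d  %3d  %s", r$gene, r$nPatientsMutated,
      r$totalMutations, if (r$isEpigenetic) "*" else "")
  }
  w("")
  b <- report$burden
  w("Epigenetic burden: %s%% of mutations (%d of %d); %s%% of samples",
    pctHalfUp(b$fractionOfMutations$x, b$fractionOfMutations$n),
    b$fractionOfMutations$x, b$fractionOfMutations$n,
    pctHalfUp(b$fractionSamplesGe1$x, b$fractionSamplesGe1$n))
  w("  with >=1 epigenetic mutation; %s%% with >1 epigenetic gene",
    pctHalfUp(b$fractionSamplesGt1$x, b$fractionSamplesGt1$n))
  w("")
  w("UV spectrum (%% of all events):")
  for (cl in UV_CLASSES)
    w("  %-28s %4d (%s%%)", cl, js$uv$counts[[cl]],
      js$uv$pctOfAllEvents[[cl]])
  w("  UVB signature total: %d of %d (%s%%)", tot$nUvbEvents,
    tot$nEvents, js$uv$pct_uvb_of_events)
  w("")
  z <- report$zTest
  w("Epigenetic share of top genes vs panel: z = %.2f, p = %.3f",
    z@statistic, z@pValue)
  t <- report$tTest
  w("UVB per gene, epigenetic (mean %.1f) vs non-epigenetic (%.1f):",
    report$uvbDistributions$epigenetic$mean,
    report$uvbDistributions$non_epigenetic$mean)
  w("  t = %.2f (df = %.1f), p = %.3f", t@statistic, t@df, t@pValue)
  invisible(c(p("summary.json"), p("events.tsv"), p("removed.tsv"),
              p("report.txt")))
}

.cfgGet <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Simulate a cohort from a YAML/JSON config
#'
#' Config keys: `seed` (mandatory), `out_dir` (default "simulated"),
#' and any [SimConfig] parameter under their R names (e.g.
#' `n_samples`, `mean_mutations_per_sample`, `uvb_single_frac`).
#' Invalid mixtures abort with a message naming the fields.
#'
#' @param configPath path to a YAML (or JSON) config file.
#' @return invisibly, the output file paths.
#' @export
cmdSimulate <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  if (is.null(cfg$seed)) stop("config must set 'seed'")
  sc <- SimConfig(
    seed = cfg$seed,
    nSamples = .cfgGet(cfg, "n_samples", 38L),
    panelSize = .cfgGet(cfg, "panel_size", 275L),
    nEpigenetic = .cfgGet(cfg, "n_epigenetic", 41L),
    meanMutationsPerSample = .cfgGet(cfg, "mean_mutations_per_sample", 20),
    dispersion = .cfgGet(cfg, "dispersion", 0.9045),
    epigeneticRateMultiplier =
      .cfgGet(cfg, "epigenetic_rate_multiplier", 1.6),
    uvbSingleFrac = .cfgGet(cfg, "uvb_single_frac", 0.70),
    uvbCcTtFrac = .cfgGet(cfg, "uvb_cc_tt_frac", 0.016),
    uvbDinucFrac = .cfgGet(cfg, "uvb_dinuc_frac", 0.012),
    uvaFrac = .cfgGet(cfg, "uva_frac", 0.05),
    indelFrac = .cfgGet(cfg, "indel_frac", 0.02),
    spliceFrac = .cfgGet(cfg, "splice_frac", 0.02),
    zipfExponent = .cfgGet(cfg, "zipf_exponent", 0.5))
  sim <- simulateCohort(sc)
  invisible(writeSimulatedCohort(sim, .cfgGet(cfg, "out_dir",
                                              "simulated")))
}

#' Analyze a cohort from a YAML/JSON config
#'
#' Config keys: `mutations` (mutation table path), `models_tsv` and
#' `models_fasta` (transcript models), `registry` (optional, defaults
#' to the shipped registry), `panel` (optional gene list/BED),
#' `annotations` (optional QC sidecar TSV), `out_dir` (default
#' "report"), plus `mode`, `denominator_mode`, `top_n`, `n_samples`,
#' `welch`.  Writes the report bundle and echoes the configuration into
#' `provenance.json`.
#'
#' @param configPath path to a YAML (or JSON) config file.
#' @return invisibly, the [analyzeCohort()] result.
#' @export
cmdAnalyze <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  for (key in c("mutations", "models_tsv", "models_fasta"))
    if (is.null(cfg[[key]])) stop("config must set '", key, "'")
  registry <- if (!is.null(cfg$registry))
    readEpigeneticRegistry(cfg$registry) else defaultRegistry()
  panel <- if (!is.null(cfg$panel)) readPanel(cfg$panel) else NULL
  models <- readTranscriptModels(cfg$models_tsv, cfg$models_fasta)
  if (is.null(panel))
    panel <- PanelDefinition(unique(c(names(models),
                                      registryGenes(registry))))
  tab <- readMutationTable(cfg$mutations, panel = panel)
  annotations <- if (!is.null(cfg$annotations))
    read.delim(cfg$annotations, stringsAsFactors = FALSE) else NULL
  report <- analyzeCohort(
    tab$variants, models, registry, panel,
    nSamples = .cfgGet(cfg, "n_samples"),
    annotations = annotations,
    mode = .cfgGet(cfg, "mode", "literal"),
    denominatorMode = .cfgGet(cfg, "denominator_mode", "mutated_genes"),
    topN = .cfgGet(cfg, "top_n", 40L),
    welch = isTRUE(cfg$welch))
  outDir <- .cfgGet(cfg, "out_dir", "report")
  writeReportBundle(report, outDir)
  write.table(tab$rejects, file.path(outDir, "rejects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = cfg,
         package_version = as.character(utils::packageVersion("EpiMutSig"))),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE)
  invisible(report)
}
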