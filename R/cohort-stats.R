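## Cohort tallies, gene rankings, epigenetic burden, per-gene UVB
## distributions and the clinicopathologic association scan.

#' Summarize a cohort of non-silent mutation events
#'
#' Builds per-gene tallies (total mutations, patients mutated, UVB and
#' nonsense counts), per-sample tallies (total, epigenetic events,
#' distinct epigenetic genes, UVB events), and overall totals by
#' consequence class, UV class and epigenetic category.  Per-sample
#' summary statistics (mean/median/sd) are computed over all `nSamples`
#' samples, counting samples without any event as zero.
#'
#' @param events data.frame of non-silent events with columns sample_id,
#'   gene, consequence, uv_class.
#' @param registry an [EpigeneticRegistry].
#' @param panel a [PanelDefinition].
#' @param nSamples number of samples in the cohort; must be >= the
#'   number of distinct sample ids in `events`.
#' @return a [CohortSummary].
#' @export
summarizeCohort <- function(events, registry, panel, nSamples) {
  if (!nrow(events)) stop("no events to summarize")
  silent <- !events$consequence %in% NON_SILENT_CLASSES
  if (any(silent))
    stop("summarizeCohort expects non-silent events only; found ",
         sum(silent), " silent/non-coding event(s)")
  samples <- unique(events$sample_id)
  if (nSamples < length(samples))
    stop(sprintf("nSamples (%d) < number of distinct sample ids (%d)",
                 nSamples, length(samples)))
  epiCat <- registryCategory(registry, events$gene)
  isEpi <- !is.na(epiCat)
  isUvb <- events$uv_class %in% UVB_CLASSES

  gsp <- split(seq_len(nrow(events)), events$gene)
  pg <- data.frame(
    gene = names(gsp),
    totalMutations = vapply(gsp, length, 1L),
    nPatientsMutated = vapply(gsp, function(i)
      length(unique(events$sample_id[i])), 1L),
    uvbMutations = vapply(gsp, function(i) sum(isUvb[i]), 1L),
    nonsenseMutations = vapply(gsp, function(i)
      sum(events$consequence[i] == "NONSENSE"), 1L),
    stringsAsFactors = FALSE)
  pg$isEpigenetic <- pg$gene %in% registryGenes(registry)
  rownames(pg) <- NULL

  ssp <- split(seq_len(nrow(events)), events$sample_id)
  ps <- data.frame(
    sampleId = names(ssp),
    totalMutations = vapply(ssp, length, 1L),
    epigeneticMutations = vapply(ssp, function(i) sum(isEpi[i]), 1L),
    epigeneticGenes = vapply(ssp, function(i)
      length(unique(events$gene[i][isEpi[i]])), 1L),
    uvbMutations = vapply(ssp, function(i) sum(isUvb[i]), 1L),
    stringsAsFactors = FALSE)
  rownames(ps) <- NULL

  counts <- c(ps$totalMutations, rep(0L, nSamples - nrow(ps)))
  stats <- c(mean = mean(counts), median = median(counts),
             sd = if (length(counts) > 1L) sd(counts) else 0,
             min = min(counts), max = max(counts))

  totals <- list(
    byConsequence = table(factor(events$consequence,
                                 levels = CONSEQUENCE_CLASSES)),
    byUv = table(factor(events$uv_class, levels = UV_CLASSES)),
    byEpigeneticCategory = table(factor(epiCat,
                                        levels = EPIGENETIC_CATEGORIES)),
    nEvents = nrow(events),
    nEpigeneticEvents = sum(isEpi),
    nUvbEvents = sum(isUvb))

  new("CohortSummary", perGene = pg, perSample = ps, totals = totals,
      nSamples = as.integer(nSamples),
      nGenesMutated = nrow(pg), panelGenes = panelGenes(panel),
      epigeneticGenes = registryGenes(registry), perSampleStats = stats)
}

#' Rank genes by recurrence
#'
#' Orders genes by number of patients mutated (descending), then total
#' mutations (descending), then gene symbol (ascending, the documented
#' deterministic tie-break), truncated to the top `n`.
#'
#' @param summary a [CohortSummary].
#' @param n number of genes to keep (>= 1); the full list when `n`
#'   exceeds the number of mutated genes.
#' @return data.frame: gene, nPatientsMutated, totalMutations,
#'   isEpigenetic.
#' @export
rankGenes <- function(summary, n = 40L) {
  stopifnot(n >= 1)
  pg <- summary@perGene
  ord <- order(-pg$nPatientsMutated, -pg$totalMutations, pg$gene)
  out <- pg[ord, c("gene", "nPatientsMutated", "totalMutations",
                   "isEpigenetic")]
  rownames(out) <- NULL
  head(out, n)
}

#' Epigenetic mutation burden
#'
#' Three proportions with exact binomial confidence intervals: the
#' fraction of all events hitting an epigenetic regulator, the fraction
#' of samples with at least one epigenetic event, and the fraction of
#' samples with more than one distinct epigenetic gene mutated.
#'
#' @param summary a [CohortSummary].
#' @param conf confidence level (default 0.95).
#' @return list of three lists (fractionOfMutations, fractionSamplesGe1,
#'   fractionSamplesGt1), each with x, n, fraction, ciLow, ciHigh.
#' @export
epigeneticBurden <- function(summary, conf = 0.95) {
  tot <- summary@totals
  ps <- summary@perSample
  prop <- function(x, n) {
    ci <- clopperPearson(x, n, conf)
    list(x = x, n = n, fraction = if (n > 0) x / n else 0,
         ciLow = ci[1], ciHigh = ci[2])
  }
  list(
    fractionOfMutations = prop(tot$nEpigeneticEvents, tot$nEvents),
    fractionSamplesGe1 = prop(sum(ps$epigeneticMutations >= 1),
                              summary@nSamples),
    fractionSamplesGt1 = prop(sum(ps$epigeneticGenes > 1),
                              summary@nSamples))
}

.modeSmallest <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[tab == max(tab)])[1]  # smallest modal value
}

#' Per-gene UVB-count distribution for a gene group
#'
#' Summary statistics over per-gene UVB-signature mutation counts for
#' the epigenetic or non-epigenetic gene group.  Under the default
#' `"mutated_genes"` denominator only genes with at least one non-silent
#' mutation contribute; under `"all_panel_genes"` every panel gene of
#' the group contributes, unmutated genes counting zero.  The mode of a
#' multimodal distribution is reported as the smallest modal value.
#'
#' @param summary a [CohortSummary].
#' @param group `"epigenetic"` or `"non_epigenetic"`.
#' @param denominatorMode `"mutated_genes"` (default) or
#'   `"all_panel_genes"`.
#' @return list(mean, median, mode, sd, n, values).
#' @export
uvbPerGeneDistribution <- function(summary,
                                   group = c("epigenetic",
                                             "non_epigenetic"),
                                   denominatorMode = c("mutated_genes",
                                                       "all_panel_genes")) {
  group <- match.arg(group)
  denominatorMode <- match.arg(denominatorMode)
  pg <- summary@perGene
  epi <- summary@epigeneticGenes
  groupGenes <- if (group == "epigenetic") {
    intersect(summary@panelGenes, epi)
  } else setdiff(summary@panelGenes, epi)
  if (denominatorMode == "mutated_genes") {
    values <- pg$uvbMutations[pg$gene %in% groupGenes]
  } else {
    values <- setNames(rep(0L, length(groupGenes)), groupGenes)
    hit <- pg$gene %in% groupGenes
    values[pg$gene[hit]] <- pg$uvbMutations[hit]
    values <- unname(values)
  }
  if (!length(values))
    stop("empty gene group '", group, "' under denominator mode '",
         denominatorMode, "'")
  list(mean = mean(values), median = median(values),
       mode = .modeSmallest(values), sd = sd(values),
       n = length(values), values = values)
}

#' Clinicopathologic association scan
#'
#' For a gene or epigenetic category, tests whether mutation presence in
#' primary melanomas associates with ulceration (2x2 Pearson
#' chi-square), Breslow depth (two-sample t) or mitotic rate (two-sample
#' t).  No multiple-testing correction is applied (raw p-values are
#' returned with the number of tests performed); tests with a degenerate
#' margin or fewer than two informative samples per group are marked
#' not-computable.
#'
#' @param events annotated event data.frame (sample_id, gene columns;
#'   epigenetic_category column used for category targets).
#' @param clinical clinical data.frame (see [readClinicalTable()]).
#' @param target a gene symbol or one of [EPIGENETIC_CATEGORIES].
#' @param welch logical, passed to [twoSampleT()].
#' @return named list of [TestResult] (ulceration, breslow,
#'   mitotic_rate) with attribute `nTests`.
#' @export
associateClinical <- function(events, clinical, target, welch = FALSE) {
  prim <- clinical[clinical$specimen_class == "primary", , drop = FALSE]
  if (nrow(prim) < 2) stop("need at least 2 primary samples")
  mutSamples <- if (target %in% EPIGENETIC_CATEGORIES) {
    unique(events$sample_id[!is.na(events$epigenetic_category) &
                              events$epigenetic_category == target])
  } else {
    unique(events$sample_id[events$gene == toupper(target)])
  }
  mutated <- prim$sample_id %in% mutSamples

  ulcer <- prim$ulceration
  ok <- !is.na(ulcer)
  ulcTest <- if (sum(ok) >= 2) {
    chiSquare2x2(sum(mutated[ok] & ulcer[ok]),
                 sum(mutated[ok] & !ulcer[ok]),
                 sum(!mutated[ok] & ulcer[ok]),
                 sum(!mutated[ok] & !ulcer[ok]))
  } else TestResult("Pearson chi-square 2x2", computable = FALSE)

  contTest <- function(values, label) {
    ok <- !is.na(values)
    g1 <- values[ok & mutated]; g2 <- values[ok & !mutated]
    if (length(g1) >= 2 && length(g2) >= 2) twoSampleT(g1, g2, welch)
    else TestResult(label, computable = FALSE,
                    inputs = list(n1 = length(g1), n2 = length(g2)))
  }
  out <- list(ulceration = ulcTest,
              breslow = contTest(prim$breslow_mm, "Student two-sample t"),
              mitotic_rate = contTest(prim$mitotic_rate_per_mm2,
                                      "Student two-sample t"))
  attr(out, "nTests") <- sum(vapply(out, isComputable, TRUE))
  out
}
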