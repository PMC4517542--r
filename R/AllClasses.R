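#' @include EpiMutSig-package.R
NULL

## Controlled vocabularies -----------------------------------------------

#' Controlled vocabularies
#'
#' Character vectors enumerating the consequence taxonomy, the UV-signature
#' taxonomy, and the epigenetic-regulator functional categories used
#' throughout the package.
#'
#' @details `NON_SILENT_CLASSES` is the subset of `CONSEQUENCE_CLASSES`
#'   counted in "non-silent" tallies: synonymous (`SILENT`) and
#'   `NONCODING_OTHER` events are excluded.  The three `UVB_*` values of
#'   `UV_CLASSES` together form the UVB signature; `UVA_G_TO_T` is the
#'   single G>T substitution attributed to UVA-induced oxidative damage.
#'
#' @name vocabularies
#' @aliases CONSEQUENCE_CLASSES NON_SILENT_CLASSES UV_CLASSES UVB_CLASSES
#'   EPIGENETIC_CATEGORIES
NULL

#' @rdname vocabularies
#' @export
CONSEQUENCE_CLASSES <- c("MISSENSE", "NONSENSE", "SILENT",
                         "FRAMESHIFT_INDEL", "IN_FRAME_INDEL",
                         "SPLICE_SITE", "NONCODING_OTHER")

#' @rdname vocabularies
#' @export
NON_SILENT_CLASSES <- c("MISSENSE", "NONSENSE", "FRAMESHIFT_INDEL",
                        "IN_FRAME_INDEL", "SPLICE_SITE")

#' @rdname vocabularies
#' @export
UV_CLASSES <- c("UVB_SINGLE_C_TO_T", "UVB_CC_TO_TT",
                "UVB_C_TO_T_IN_DINUCLEOTIDE", "UVA_G_TO_T", "OTHER")

#' @rdname vocabularies
#' @export
UVB_CLASSES <- c("UVB_SINGLE_C_TO_T", "UVB_CC_TO_TT",
                 "UVB_C_TO_T_IN_DINUCLEOTIDE")

#' @rdname vocabularies
#' @export
EPIGENETIC_CATEGORIES <- c("DNA_METHYLATION_DEMETHYLATION",
                           "HISTONE_MODIFICATION",
                           "CHROMATIN_REMODELING",
                           "MIRNA_PROCESSING")

## PanelDefinition --------------------------------------------------------

#' Gene-panel definition
#'
#' An ordered set of unique, case-normalized gene symbols with optional
#' per-gene genomic intervals, describing a targeted sequencing panel
#' (e.g. a 275-gene cancer panel).
#'
#' @slot genes character vector of unique upper-cased gene symbols.
#' @slot intervals a [GenomicRanges::GRanges] of panel target intervals
#'   (with a `gene` metadata column) or `NULL`.
#'
#' @seealso [readPanel()], [panelGenes()]
#' @export
setClass("PanelDefinition",
         representation(genes = "character", intervals = "ANY"),
         prototype(genes = character(), intervals = NULL))

setValidity("PanelDefinition", function(object) {
  g <- object@genes
  if (anyDuplicated(g)) return("panel gene symbols must be unique")
  if (any(g != toupper(g))) return("panel gene symbols must be upper case")
  if (!is.null(object@intervals) && !is(object@intervals, "GRanges"))
    return("intervals must be NULL or a GRanges")
  TRUE
})

#' @describeIn PanelDefinition constructor.
#' @param genes character vector of gene symbols (case-normalized on entry).
#' @param intervals optional `GRanges` of target intervals.
#' @export
PanelDefinition <- function(genes, intervals = NULL) {
  new("PanelDefinition", genes = toupper(as.character(genes)),
      intervals = intervals)
}

#' @describeIn PanelDefinition accessor for the gene symbols.
#' @param panel a `PanelDefinition`.
#' @export
panelGenes <- function(panel) panel@genes

setMethod("show", "PanelDefinition", function(object) {
  cat("PanelDefinition with", length(object@genes), "genes",
      if (is.null(object@intervals)) "(no intervals)\n" else
        sprintf("and %d target intervals\n", length(object@intervals)))
})

#' @describeIn PanelDefinition number of panel genes.
#' @param x a `PanelDefinition`.
#' @export
setMethod("length", "PanelDefinition", function(x) length(x@genes))

## EpigeneticRegistry -----------------------------------------------------

#' Epigenetic-regulator registry
#'
#' Maps gene symbols to exactly one of the four epigenetic functional
#' categories: DNA methylation/demethylation, histone modification,
#' chromatin remodeling, or miRNA processing.
#'
#' @slot entries named character vector: names are upper-cased gene
#'   symbols, values are categories from [EPIGENETIC_CATEGORIES].
#'
#' @seealso [readEpigeneticRegistry()], [defaultRegistry()]
#' @export
setClass("EpigeneticRegistry",
         representation(entries = "character"),
         prototype(entries = character()))

setValidity("EpigeneticRegistry", function(object) {
  e <- object@entries
  if (length(e) && is.null(names(e))) return("entries must be named by gene")
  if (anyDuplicated(names(e))) return("duplicate gene in registry")
  bad <- setdiff(unique(e), EPIGENETIC_CATEGORIES)
  if (length(bad))
    return(paste("unknown category:", paste(bad, collapse = ", ")))
  TRUE
})

#' @describeIn EpigeneticRegistry constructor from a named character
#'   vector (names = genes, values = categories).
#' @param entries named character vector.
#' @export
EpigeneticRegistry <- function(entries = character()) {
  if (length(entries)) names(entries) <- toupper(names(entries))
  new("EpigeneticRegistry", entries = entries)
}

#' @describeIn EpigeneticRegistry gene symbols in the registry.
#' @param registry an `EpigeneticRegistry`.
#' @export
registryGenes <- function(registry) {
  if (length(registry@entries)) names(registry@entries) else character(0)
}

#' @describeIn EpigeneticRegistry category for each of `genes`
#'   (`NA` for genes not in the registry).
#' @param genes character vector of gene symbols.
#' @export
registryCategory <- function(registry, genes) {
  unname(registry@entries[toupper(genes)])
}

#' @describeIn EpigeneticRegistry number of registry genes.
#' @param x an `EpigeneticRegistry`.
#' @export
setMethod("length", "EpigeneticRegistry", function(x) length(x@entries))

setMethod("show", "EpigeneticRegistry", function(object) {
  cat("EpigeneticRegistry with", length(object@entries), "genes\n")
  if (length(object@entries)) {
    tab <- table(factor(object@entries, levels = EPIGENETIC_CATEGORIES))
    for (nm in names(tab)) cat(sprintf("  %-30s %d\n", nm, tab[[nm]]))
  }
})

## TranscriptModel --------------------------------------------------------

#' Minimal transcript model
#'
#' A toy gene model for consequence calling: strand, ordered 1-based
#' inclusive genomic coding intervals, and the plus-strand reference
#' sequence over those intervals (concatenated in genomic order).  The
#' coding sequence (5'->3') is this concatenation for `+` strand genes
#' and its reverse complement for `-` strand genes.
#'
#' @slot gene gene symbol.
#' @slot chrom chromosome/contig label.
#' @slot strand `"+"` or `"-"`.
#' @slot starts,ends integer vectors of interval starts/ends (1-based,
#'   inclusive, sorted, non-overlapping).
#' @slot sequence plus-strand reference sequence over the intervals,
#'   concatenated in genomic order; total length divisible by 3.
#' @slot spliceWindow integer, number of intronic bases flanking each
#'   internal exon boundary considered splice-site territory (default 2,
#'   the canonical GT/AG dinucleotides).
#'
#' @seealso [classifySnv()], [readTranscriptModels()]
#' @export
setClass("TranscriptModel",
         representation(gene = "character", chrom = "character",
                        strand = "character", starts = "integer",
                        ends = "integer", sequence = "character",
                        spliceWindow = "integer"),
         prototype(spliceWindow = 2L))

setValidity("TranscriptModel", function(object) {
  s <- object@starts; e <- object@ends
  if (length(s) != length(e) || !length(s))
    return("starts and ends must be non-empty and of equal length")
  if (any(e < s)) return("interval end before start")
  if (is.unsorted(s, strictly = TRUE) ||
      (length(s) > 1L && any(s[-1L] <= e[-length(e)])))
    return("intervals must be sorted and non-overlapping")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  L <- sum(e - s + 1L)
  if (nchar(object@sequence) != L)
    return("sequence length must equal total interval length")
  if (L %% 3L != 0L) return("coding length must be divisible by 3")
  if (object@spliceWindow < 0L) return("spliceWindow must be >= 0")
  TRUE
})

#' @describeIn TranscriptModel constructor.
#' @param gene,chrom,strand,starts,ends,sequence,spliceWindow see slots.
#' @export
TranscriptModel <- function(gene, chrom, strand, starts, ends, sequence,
                            spliceWindow = 2L) {
  new("TranscriptModel", gene = toupper(gene), chrom = as.character(chrom),
      strand = strand, starts = as.integer(starts), ends = as.integer(ends),
      sequence = toupper(as.character(sequence)),
      spliceWindow = as.integer(spliceWindow))
}

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (%s%s): %d coding interval(s), CDS %d nt\n",
              object@gene, object@chrom, object@strand,
              length(object@starts), nchar(object@sequence)))
})

## QcConfig ---------------------------------------------------------------

#' Variant and sample QC thresholds
#'
#' Thresholds for the tumor-only QC rules: samples with mean target
#' coverage below `minMeanCoverage` are failed; variants with population
#' allele frequency above `maxPopulationAf` (or present in a common-SNP
#' database, when `dbsnpFilter` is on) are filtered as germline unless
#' rescued by a somatic whitelist; variants below `reviewAlleleFraction`
#' allele fraction or `reviewSiteCoverage` site coverage are flagged for
#' manual review but retained.
#'
#' @slot minMeanCoverage reads, default 50.
#' @slot reviewAlleleFraction proportion, default 0.10.
#' @slot reviewSiteCoverage reads, default 50.
#' @slot maxPopulationAf proportion, default 0.001.
#' @slot dbsnpFilter logical; whether common-SNP-database membership
#'   alone (without a population frequency) triggers the germline filter.
#'
#' @seealso [qcSample()], [filterVariant()], [applyQc()]
#' @export
setClass("QcConfig",
         representation(minMeanCoverage = "numeric",
                        reviewAlleleFraction = "numeric",
                        reviewSiteCoverage = "numeric",
                        maxPopulationAf = "numeric",
                        dbsnpFilter = "logical"),
         prototype(minMeanCoverage = 50, reviewAlleleFraction = 0.10,
                   reviewSiteCoverage = 50, maxPopulationAf = 0.001,
                   dbsnpFilter = TRUE))

setValidity("QcConfig", function(object) {
  if (object@minMeanCoverage <= 0 || object@reviewSiteCoverage <= 0)
    return("coverage thresholds must be positive")
  if (object@reviewAlleleFraction <= 0 || object@reviewAlleleFraction >= 1)
    return("reviewAlleleFraction must be in (0,1)")
  if (object@maxPopulationAf <= 0 || object@maxPopulationAf >= 1)
    return("maxPopulationAf must be in (0,1)")
  TRUE
})

#' @describeIn QcConfig constructor.
#' @param minMeanCoverage,reviewAlleleFraction,reviewSiteCoverage,maxPopulationAf,dbsnpFilter see slots.
#' @export
QcConfig <- function(minMeanCoverage = 50, reviewAlleleFraction = 0.10,
                     reviewSiteCoverage = 50, maxPopulationAf = 0.001,
                     dbsnpFilter = TRUE) {
  new("QcConfig", minMeanCoverage = minMeanCoverage,
      reviewAlleleFraction = reviewAlleleFraction,
      reviewSiteCoverage = reviewSiteCoverage,
      maxPopulationAf = maxPopulationAf, dbsnpFilter = dbsnpFilter)
}

setMethod("show", "QcConfig", function(object) {
  cat(sprintf(paste0("QcConfig: sample fail <%gX mean coverage; review ",
                     "<%g AF or <%gX site coverage; germline filter ",
                     ">%g population AF%s\n"),
              object@minMeanCoverage, object@reviewAlleleFraction,
              object@reviewSiteCoverage, object@maxPopulationAf,
              if (object@dbsnpFilter) " (or SNP-database member)" else ""))
})

## TestResult -------------------------------------------------------------

#' Result of an inferential test
#'
#' Container for a test statistic, its degrees of freedom (if any), the
#' two-sided p-value, an optional confidence interval, the point
#' estimate the interval covers, and an echo of the inputs tested.
#'
#' @slot method label of the test performed.
#' @slot statistic test statistic (NA when not computable).
#' @slot df degrees of freedom or NA.
#' @slot pValue two-sided p-value or NA.
#' @slot estimate point estimate (e.g. difference in proportions) or NA.
#' @slot ciLow,ciHigh confidence bounds or NA.
#' @slot computable FALSE for degenerate inputs (e.g. empty margin).
#' @slot inputs list echoing the counts/summaries tested.
#'
#' @export
setClass("TestResult",
         representation(method = "character", statistic = "numeric",
                        df = "numeric", pValue = "numeric",
                        estimate = "numeric", ciLow = "numeric",
                        ciHigh = "numeric", computable = "logical",
                        inputs = "list"),
         prototype(method = "", statistic = NA_real_, df = NA_real_,
                   pValue = NA_real_, estimate = NA_real_,
                   ciLow = NA_real_, ciHigh = NA_real_,
                   computable = TRUE, inputs = list()))

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (!is.na(p) && (p < 0 || p > 1)) return("p-value outside [0,1]")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      !is.na(object@estimate)) {
    if (object@ciLow > object@estimate + 1e-12 ||
        object@ciHigh < object@estimate - 1e-12)
      return("confidence interval must contain the point estimate")
  }
  TRUE
})

TestResult <- function(method, statistic = NA_real_, df = NA_real_,
                       pValue = NA_real_, estimate = NA_real_,
                       ciLow = NA_real_, ciHigh = NA_real_,
                       computable = TRUE, inputs = list()) {
  new("TestResult", method = method, statistic = as.numeric(statistic),
      df = as.numeric(df), pValue = as.numeric(pValue),
      estimate = as.numeric(estimate), ciLow = as.numeric(ciLow),
      ciHigh = as.numeric(ciHigh), computable = computable, inputs = inputs)
}

#' @describeIn TestResult test statistic.
#' @param x a `TestResult`.
#' @export
statistic <- function(x) x@statistic

#' @describeIn TestResult two-sided p-value.
#' @export
pValue <- function(x) x@pValue

#' @describeIn TestResult confidence interval as `c(lower, upper)`.
#' @export
confInt <- function(x) c(x@ciLow, x@ciHigh)

#' @describeIn TestResult whether the test was computable.
#' @export
isComputable <- function(x) x@computable

setMethod("show", "TestResult", function(object) {
  if (!object@computable) {
    cat(sprintf("%s: not computable (degenerate input)\n", object@method))
    return(invisible(NULL))
  }
  cat(sprintf("%s: statistic = %.4g%s, two-sided p = %.4g\n",
              object@method, object@statistic,
              if (is.na(object@df)) "" else sprintf(" (df = %.4g)", object@df),
              object@pValue))
  if (!is.na(object@ciLow))
    cat(sprintf("  estimate %.4g, 95%% CI [%.4g, %.4g]\n",
                object@estimate, object@ciLow, object@ciHigh))
})

## CohortSummary ----------------------------------------------------------

#' Cohort-level tallies
#'
#' Per-gene and per-sample tallies over non-silent mutation events, with
#' overall totals by consequence class, UV class and epigenetic
#' category.  Produced by [summarizeCohort()].
#'
#' @slot perGene data.frame: gene, totalMutations, nPatientsMutated,
#'   uvbMutations, nonsenseMutations, isEpigenetic.
#' @slot perSample data.frame: sampleId, totalMutations,
#'   epigeneticMutations, epigeneticGenes, uvbMutations.
#' @slot totals named list of count tables (byConsequence, byUv,
#'   byEpigeneticCategory, nEvents, nEpigeneticEvents, nUvbEvents).
#' @slot nSamples number of samples in the cohort (samples without any
#'   event count as zeros in the per-sample statistics).
#' @slot nGenesMutated number of distinct genes with >= 1 event.
#' @slot panelGenes panel gene symbols.
#' @slot epigeneticGenes registry gene symbols.
#' @slot perSampleStats named numeric vector (mean, median, sd, min, max)
#'   of per-sample mutation counts, zero-padded to `nSamples`.
#'
#' @export
setClass("CohortSummary",
         representation(perGene = "data.frame", perSample = "data.frame",
                        totals = "list", nSamples = "integer",
                        nGenesMutated = "integer", panelGenes = "character",
                        epigeneticGenes = "character",
                        perSampleStats = "numeric"))

#' @describeIn CohortSummary per-gene tally table.
#' @param summary a `CohortSummary`.
#' @export
perGene <- function(summary) summary@perGene

#' @describeIn CohortSummary per-sample tally table.
#' @export
perSample <- function(summary) summary@perSample

#' @describeIn CohortSummary totals list.
#' @export
cohortTotals <- function(summary) summary@totals

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf(paste0("CohortSummary: %d non-silent events in %d of %d ",
                     "genes across %d samples\n"),
              object@totals$nEvents, object@nGenesMutated,
              length(object@panelGenes), object@nSamples))
  cat(sprintf("  mean %.1f / median %.1f / sd %.1f mutations per sample\n",
              object@perSampleStats[["mean"]],
              object@perSampleStats[["median"]],
              object@perSampleStats[["sd"]]))
  cat(sprintf("  epigenetic events: %d (%s%%)\n",
              object@totals$nEpigeneticEvents,
              pctHalfUp(object@totals$nEpigeneticEvents,
                        object@totals$nEvents)))
})

## SimConfig --------------------------------------------------------------

#' Synthetic-cohort configuration
#'
#' Parameters for [simulateCohort()].  Defaults emulate a 38-sample,
#' 275-gene melanoma panel cohort with about 20 non-silent mutations per
#' sample (heavy-tailed: SD ~ 21.5 via a negative binomial), a 41-gene
#' epigenetic subset mutated at 1.6x the background rate, and a
#' UVB-dominated substitution-process mixture (70% single C>T, 1.6%
#' tandem CC>TT, 1.2% other C>T-bearing dinucleotides, 5% G>T, small
#' indel and splice fractions, remainder background substitutions).
#'
#' @slot seed integer RNG seed (mandatory).
#' @slot nSamples number of samples (default 38).
#' @slot panelSize number of panel genes (default 275).
#' @slot nEpigenetic number of epigenetic-regulator genes (default 41).
#' @slot meanMutationsPerSample negative-binomial mean (default 20).
#' @slot dispersion negative-binomial size parameter (default 0.9045,
#'   i.e. mu^2/(var - mu) for mean 20 and SD 21.5).
#' @slot epigeneticRateMultiplier per-gene rate multiplier for
#'   epigenetic genes (default 1.6).
#' @slot uvbSingleFrac,uvbCcTtFrac,uvbDinucFrac,uvaFrac,indelFrac,spliceFrac
#'   event-class mixture proportions (defaults 0.70, 0.016, 0.012, 0.05,
#'   0.02, 0.02); the remainder is background (OTHER) substitutions.
#' @slot zipfExponent exponent of the Zipf-like per-gene weight law
#'   (default 0.5).
#'
#' @seealso [simulateCohort()], [recoverParameters()]
#' @export
setClass("SimConfig",
         representation(seed = "integer", nSamples = "integer",
                        panelSize = "integer", nEpigenetic = "integer",
                        meanMutationsPerSample = "numeric",
                        dispersion = "numeric",
                        epigeneticRateMultiplier = "numeric",
                        uvbSingleFrac = "numeric", uvbCcTtFrac = "numeric",
                        uvbDinucFrac = "numeric", uvaFrac = "numeric",
                        indelFrac = "numeric", spliceFrac = "numeric",
                        zipfExponent = "numeric"))

setValidity("SimConfig", function(object) {
  fr <- c(object@uvbSingleFrac, object@uvbCcTtFrac, object@uvbDinucFrac,
          object@uvaFrac, object@indelFrac, object@spliceFrac)
  if (any(fr < 0) || any(fr > 1))
    return("mixture proportions must lie in [0,1]")
  if (sum(fr) > 1)
    return(sprintf("mixture proportions sum to %.3f > 1 %s", sum(fr),
                   "(uvbSingleFrac + uvbCcTtFrac + uvbDinucFrac + uvaFrac + indelFrac + spliceFrac)"))
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  if (object@nSamples < 1L || object@panelSize < 2L)
    return("nSamples >= 1 and panelSize >= 2 required")
  if (object@nEpigenetic < 1L || object@nEpigenetic >= object@panelSize)
    return("nEpigenetic must be in [1, panelSize)")
  if (object@meanMutationsPerSample <= 0 || object@dispersion <= 0)
    return("meanMutationsPerSample and dispersion must be positive")
  if (object@epigeneticRateMultiplier < 0)
    return("epigeneticRateMultiplier must be >= 0")
  TRUE
})

#' @describeIn SimConfig constructor.
#' @param seed,nSamples,panelSize,nEpigenetic,meanMutationsPerSample,dispersion,epigeneticRateMultiplier,uvbSingleFrac,uvbCcTtFrac,uvbDinucFrac,uvaFrac,indelFrac,spliceFrac,zipfExponent see slots.
#' @export
SimConfig <- function(seed, nSamples = 38L, panelSize = 275L,
                      nEpigenetic = 41L, meanMutationsPerSample = 20,
                      dispersion = 0.9045, epigeneticRateMultiplier = 1.6,
                      uvbSingleFrac = 0.70, uvbCcTtFrac = 0.016,
                      uvbDinucFrac = 0.012, uvaFrac = 0.05,
                      indelFrac = 0.02, spliceFrac = 0.02,
                      zipfExponent = 0.5) {
  new("SimConfig", seed = as.integer(seed), nSamples = as.integer(nSamples),
      panelSize = as.integer(panelSize), nEpigenetic = as.integer(nEpigenetic),
      meanMutationsPerSample = meanMutationsPerSample,
      dispersion = dispersion,
      epigeneticRateMultiplier = epigeneticRateMultiplier,
      uvbSingleFrac = uvbSingleFrac, uvbCcTtFrac = uvbCcTtFrac,
      uvbDinucFrac = uvbDinucFrac, uvaFrac = uvaFrac,
      indelFrac = indelFrac, spliceFrac = spliceFrac,
      zipfExponent = zipfExponent)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d samples, %d-gene panel (%d epigenetic, ",
                     "rate x%.2g), NB(mu=%g, size=%g) mutations/sample, ",
                     "seed %d\n"),
              object@nSamples, object@panelSize, object@nEpigenetic,
              object@epigeneticRateMultiplier,
              object@meanMutationsPerSample, object@dispersion, object@seed))
})
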