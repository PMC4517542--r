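## Sample- and variant-level QC and tumor-only germline filtering.
## Filtered variants leave the analysis stream; flagged ones stay in it.

QC_STATUSES <- c("PASS", "FILTERED_POPULATION_SNP", "FLAG_MANUAL_REVIEW",
                 "SAMPLE_FAILED")

#' Sample-level QC
#'
#' A sample is failed when its mean target coverage is strictly below
#' the configured minimum (default 50X); a sample at exactly the
#' threshold passes.
#'
#' @param meanTargetCoverage mean target coverage in reads (>= 0).
#' @param cfg a [QcConfig].
#' @return `"PASS"` or `"SAMPLE_FAILED"`.
#' @export
qcSample <- function(meanTargetCoverage, cfg = QcConfig()) {
  if (any(is.na(meanTargetCoverage)) || any(meanTargetCoverage < 0))
    stop("meanTargetCoverage must be non-negative")
  ifelse(meanTargetCoverage < cfg@minMeanCoverage, "SAMPLE_FAILED", "PASS")
}

#' Variant-level germline filter and review flags
#'
#' Applies the tumor-only germline filter and the manual-review flags to
#' one variant.  The population filter fires when the population allele
#' frequency exceeds the threshold (default 0.1%) or, when the database
#' rule is enabled, the variant is a known common-SNP-database member;
#' membership in a somatic whitelist (COSMIC-like) overrides the filter
#' and routes the variant to manual review instead.  Independently, a
#' low allele fraction (< 10%) or low site coverage (< 50X) adds a
#' manual-review flag; flagged variants stay in the analysis stream.
#' Missing annotations skip the corresponding rule.
#'
#' @param variant one-row variant data.frame (needs `allele_fraction`
#'   and `site_coverage`; both may be NA).
#' @param populationAf population allele frequency or NA.
#' @param inWhitelist logical; somatic-whitelist membership.
#' @param dbsnpMember logical; common-SNP-database membership.
#' @param cfg a [QcConfig].
#' @return list with `status` (one of PASS, FILTERED_POPULATION_SNP,
#'   FLAG_MANUAL_REVIEW) and `reasons` (character vector of rule ids,
#'   empty only for PASS).
#' @export
filterVariant <- function(variant, populationAf = NA_real_,
                          inWhitelist = FALSE, dbsnpMember = FALSE,
                          cfg = QcConfig()) {
  reasons <- character()
  popHit <- (!is.na(populationAf) && populationAf > cfg@maxPopulationAf) ||
    (cfg@dbsnpFilter && isTRUE(dbsnpMember))
  if (popHit && !isTRUE(inWhitelist)) {
    if (!is.na(populationAf) && populationAf > cfg@maxPopulationAf)
      reasons <- c(reasons, "population_af_above_threshold")
    if (cfg@dbsnpFilter && isTRUE(dbsnpMember))
      reasons <- c(reasons, "snp_database_member")
    return(list(status = "FILTERED_POPULATION_SNP", reasons = reasons))
  }
  if (popHit && isTRUE(inWhitelist))
    reasons <- c(reasons, "whitelist_rescue")
  af <- variant$allele_fraction
  cov <- variant$site_coverage
  if (!is.null(af) && !is.na(af) && af < cfg@reviewAlleleFraction)
    reasons <- c(reasons, "low_allele_fraction")
  if (!is.null(cov) && !is.na(cov) && cov < cfg@reviewSiteCoverage)
    reasons <- c(reasons, "low_site_coverage")
  if (length(reasons))
    list(status = "FLAG_MANUAL_REVIEW", reasons = reasons)
  else
    list(status = "PASS", reasons = character())
}

#' Apply QC to a variant table
#'
#' Vectorized driver over [qcSample()] and [filterVariant()].  Variants
#' from failed samples and germline-filtered variants are moved to the
#' `removed` table with their reasons; PASS and FLAG_MANUAL_REVIEW
#' variants are kept (flags recorded in `qc_status` / `qc_reasons`
#' columns).  Conservation: every input row appears in exactly one of
#' the two outputs.
#'
#' @param variants variant data.frame (see [readMutationTable()]).
#' @param annotations optional data.frame keyed by chrom, pos, ref, alt
#'   with columns population_af, dbsnp_member, whitelist_member.
#' @param sampleCoverage optional named numeric vector of per-sample
#'   mean target coverage.
#' @param cfg a [QcConfig].
#' @return list(variants = kept rows with qc_status/qc_reasons,
#'   removed = removed rows with qc_status/qc_reasons).
#' @export
applyQc <- function(variants, annotations = NULL, sampleCoverage = NULL,
                    cfg = QcConfig()) {
  n <- nrow(variants)
  status <- character(n)
  reasons <- character(n)

  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  ann <- if (!is.null(annotations) && nrow(annotations)) {
    idx <- match(key(variants), key(annotations))
    list(pop = annotations$population_af[idx],
         db = isTRUE(cfg@dbsnpFilter) &
           !is.na(idx) & sapply(annotations$dbsnp_member[idx], isTRUE),
         wl = !is.na(idx) & sapply(annotations$whitelist_member[idx], isTRUE))
  } else {
    list(pop = rep(NA_real_, n), db = rep(FALSE, n), wl = rep(FALSE, n))
  }

  for (i in seq_len(n)) {
    if (!is.null(sampleCoverage)) {
      sc <- sampleCoverage[[variants$sample_id[i]]]
      if (!is.null(sc) && !is.na(sc) &&
          qcSample(sc, cfg) == "SAMPLE_FAILED") {
        status[i] <- "SAMPLE_FAILED"
        reasons[i] <- "sample_mean_coverage_below_minimum"
        next
      }
    }
    d <- filterVariant(variants[i, , drop = FALSE],
                       populationAf = ann$pop[i],
                       inWhitelist = ann$wl[i], dbsnpMember = ann$db[i],
                       cfg = cfg)
    status[i] <- d$status
    reasons[i] <- paste(d$reasons, collapse = ";")
  }

  out <- variants
  out$qc_status <- status
  out$qc_reasons <- reasons
  keep <- status %in% c("PASS", "FLAG_MANUAL_REVIEW")
  list(variants = out[keep, , drop = FALSE],
       removed = out[!keep, , drop = FALSE])
}
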