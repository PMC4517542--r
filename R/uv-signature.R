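## Dinucleotide merging and UV mutational-signature classification.
## Default classification is LITERAL (alleles as written): the UVA class
## is reported as G>T, matching how targeted-panel melanoma studies print
## it, rather than the strand-collapsed C>A.  Pyrimidine normalization is
## an explicit mode.

#' Merge adjacent same-sample SNVs into dinucleotide events
#'
#' Within each sample, single-nucleotide substitutions at consecutive
#' positions in the same gene are assumed cis and merged into one
#' dinucleotide event (ref/alt concatenated, position of the left
#' base).  Runs of three or more consecutive SNVs merge the leftmost
#' pair and emit the remainder singly (a message notes the run).  All
#' other variants pass through unchanged.  Count conservation: every
#' input variant appears in exactly one output event
#' (`sum(n_components) == nrow(variants)`).
#'
#' @param variants QC-passed variant data.frame.
#' @return event data.frame: sample_id, chrom, pos, ref, alt, gene,
#'   allele_fraction (mean over components), site_coverage (min),
#'   n_components.
#' @export
mergeAdjacentSnvs <- function(variants) {
  if (!nrow(variants)) {
    out <- variants[, intersect(VARIANT_COLUMNS, names(variants)),
                    drop = FALSE]
    out$n_components <- integer(0)
    return(out)
  }
  isSnv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  keyOf <- function(df) paste(df$sample_id, df$chrom, df$gene, sep = "\r")
  ord <- order(keyOf(variants), variants$pos)
  v <- variants[ord, , drop = FALSE]
  isSnv <- isSnv[ord]
  key <- keyOf(v)

  rows <- vector("list", nrow(v))
  nr <- 0L
  emit <- function(idx) {
    nr <<- nr + 1L
    first <- idx[1L]
    rows[[nr]] <<- data.frame(
      sample_id = v$sample_id[first], chrom = v$chrom[first],
      pos = v$pos[first],
      ref = paste(v$ref[idx], collapse = ""),
      alt = paste(v$alt[idx], collapse = ""),
      gene = v$gene[first],
      allele_fraction = mean(v$allele_fraction[idx]),
      site_coverage = suppressWarnings(min(v$site_coverage[idx])),
      n_components = length(idx), stringsAsFactors = FALSE)
  }

  i <- 1L
  n <- nrow(v)
  while (i <= n) {
    if (isSnv[i] && i < n && isSnv[i + 1L] && key[i + 1L] == key[i] &&
        v$pos[i + 1L] == v$pos[i] + 1L) {
      if (i + 1L < n && isSnv[i + 2L] && key[i + 2L] == key[i] &&
          v$pos[i + 2L] == v$pos[i] + 2L)
        message("run of >2 consecutive SNVs in ", v$sample_id[i], " ",
                v$gene[i], ": merging leftmost pair only")
      emit(c(i, i + 1L))
      i <- i + 2L
    } else {
      emit(i)
      i <- i + 1L
    }
  }
  out <- do.call(rbind, rows[seq_len(nr)])
  rownames(out) <- NULL
  out
}

#' Classify events by UV mutational signature
#'
#' Substitution events are matched against the UV taxonomy: single C>T
#' (`UVB_SINGLE_C_TO_T`), tandem CC>TT (`UVB_CC_TO_TT`), a dinucleotide
#' substitution containing a C>T component other than CC>TT
#' (`UVB_C_TO_T_IN_DINUCLEOTIDE`), single G>T (`UVA_G_TO_T`), otherwise
#' `OTHER`.  Indel and splice-site events always receive `OTHER`.  The
#' default `"literal"` mode matches alleles exactly as written; in
#' `"pyrimidine"` mode every component is collapsed to the pyrimidine
#' reference strand before matching, so G>A counts as C>T, GG>AA as
#' CC>TT, and C>A as the G>T (UVA) equivalent.
#'
#' @param ref,alt character vectors of event alleles.
#' @param consequence optional character vector of consequence classes;
#'   indel/splice events are forced to `OTHER`.
#' @param mode `"literal"` (default) or `"pyrimidine"`.
#' @return character vector over [UV_CLASSES].
#' @export
classifyUv <- function(ref, alt, consequence = NULL,
                       mode = c("literal", "pyrimidine")) {
  mode <- match.arg(mode)
  ref <- toupper(ref); alt <- toupper(alt)
  pyr <- mode == "pyrimidine"
  out <- rep("OTHER", length(ref))

  ## per-component equivalence under the chosen mode
  isCT <- function(r, a) (r == "C" & a == "T") |
    (pyr & r == "G" & a == "A")
  isGT <- function(r, a) (r == "G" & a == "T") |
    (pyr & r == "C" & a == "A")

  sub1 <- nchar(ref) == 1L & nchar(alt) == 1L
  out[sub1 & isCT(ref, alt)] <- "UVB_SINGLE_C_TO_T"
  out[sub1 & isGT(ref, alt)] <- "UVA_G_TO_T"

  di <- nchar(ref) == 2L & nchar(alt) == 2L
  r1 <- substr(ref, 1, 1); r2 <- substr(ref, 2, 2)
  a1 <- substr(alt, 1, 1); a2 <- substr(alt, 2, 2)
  cc <- di & ((ref == "CC" & alt == "TT") |
                (pyr & ref == "GG" & alt == "AA"))
  out[cc] <- "UVB_CC_TO_TT"
  hasCT <- di & !cc & (isCT(r1, a1) | isCT(r2, a2))
  out[hasCT] <- "UVB_C_TO_T_IN_DINUCLEOTIDE"
  if (!is.null(consequence)) {
    forced <- consequence %in% c("FRAMESHIFT_INDEL", "IN_FRAME_INDEL",
                                 "SPLICE_SITE")
    out[forced] <- "OTHER"
  }
  out
}

#' UVB-signature fraction with exact binomial CI
#'
#' Proportion of events whose UV class is one of the three UVB classes,
#' with a Clopper-Pearson 95% interval.
#'
#' @param uvClasses character vector over [UV_CLASSES].
#' @param conf confidence level (default 0.95).
#' @return list(x, n, fraction, ciLow, ciHigh).
#' @export
uvbFraction <- function(uvClasses, conf = 0.95) {
  if (!length(uvClasses)) stop("no events: UVB fraction undefined")
  x <- sum(uvClasses %in% UVB_CLASSES)
  n <- length(uvClasses)
  ci <- clopperPearson(x, n, conf)
  list(x = x, n = n, fraction = x / n, ciLow = ci[1], ciHigh = ci[2])
}
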