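## Consequence classification against minimal transcript models.
## Precedence: splice-site > coding classes; start-loss and stop-loss
## fold into MISSENSE; indels or MNVs touching an exon/intron boundary
## classify as SPLICE_SITE.

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

.geneticCode <- function() Biostrings::GENETIC_CODE

## Offset of a genomic position within the plus-strand concatenation of
## the coding intervals, or NA when intronic/outside.
.cdsOffset <- function(model, pos) {
  s <- model@starts; e <- model@ends
  i <- which(pos >= s & pos <= e)
  if (!length(i)) return(NA_integer_)
  before <- if (i > 1L) sum(e[seq_len(i - 1L)] - s[seq_len(i - 1L)] + 1L)
            else 0L
  before + (pos - s[i] + 1L)
}

#' Coding sequence of a transcript model
#'
#' The 5'->3' coding sequence: the plus-strand interval concatenation
#' for `+` strand models, its reverse complement for `-` strand models.
#'
#' @param model a [TranscriptModel].
#' @return character scalar.
#' @export
cdsSequence <- function(model) {
  if (model@strand == "+") model@sequence else .revcomp(model@sequence)
}

#' Splice-site test
#'
#' TRUE iff `pos` lies within `spliceWindow` bases intronic of an
#' internal coding-interval boundary (donor side downstream of every
#' exon but the last; acceptor side upstream of every exon but the
#' first).  Terminal transcript edges are not splice sites.
#'
#' @param model a [TranscriptModel].
#' @param pos genomic position (1-based).
#' @return logical.
#' @export
isSpliceSite <- function(model, pos) {
  w <- model@spliceWindow
  if (w == 0L) return(FALSE)
  s <- model@starts; e <- model@ends; n <- length(s)
  if (n < 2L) return(FALSE)
  donor <- any(pos > e[-n] & pos <= e[-n] + w)
  acceptor <- any(pos < s[-1L] & pos >= s[-1L] - w)
  donor || acceptor
}

## positions (genomic) whose offsets are defined; used by drivers
.inCoding <- function(model, pos) !is.na(.cdsOffset(model, pos))

.checkRef <- function(model, pos, ref) {
  off <- .cdsOffset(model, pos)
  have <- substr(model@sequence, off, off)
  if (have != ref)
    stop(sprintf("reference mismatch at %s:%d (model has %s, variant says %s)",
                 model@chrom, pos, have, ref))
  off
}

#' Classify a single-nucleotide variant
#'
#' Splice-window positions classify as `SPLICE_SITE` (precedence over
#' coding classes).  Coding positions are classified by mutating the
#' containing codon and translating with the standard nuclear genetic
#' code: stop gain is `NONSENSE`, any other amino-acid change (including
#' start or stop loss) is `MISSENSE`, a synonymous change is `SILENT`.
#' Positions outside coding intervals and splice windows are
#' `NONCODING_OTHER`.  `ref`/`alt` are plus-strand (genomic) alleles; a
#' reference mismatch against the model sequence is an error naming the
#' position.
#'
#' @param model a [TranscriptModel].
#' @param pos genomic position.
#' @param ref,alt single plus-strand bases.
#' @return one of [CONSEQUENCE_CLASSES].
#' @export
classifySnv <- function(model, pos, ref, alt) {
  if (isSpliceSite(model, pos)) return("SPLICE_SITE")
  if (!.inCoding(model, pos)) return("NONCODING_OTHER")
  off <- .checkRef(model, pos, ref)
  L <- nchar(model@sequence)
  if (model@strand == "+") {
    cdsPos <- off; calt <- alt
  } else {
    cdsPos <- L - off + 1L; calt <- unname(.COMP[alt])
  }
  cds <- cdsSequence(model)
  ci <- (cdsPos - 1L) %/% 3L
  codon <- substr(cds, ci * 3L + 1L, ci * 3L + 3L)
  within <- cdsPos - ci * 3L
  newCodon <- codon
  substr(newCodon, within, within) <- calt
  gc <- .geneticCode()
  aaOld <- unname(gc[codon]); aaNew <- unname(gc[newCodon])
  if (aaNew == aaOld) "SILENT"
  else if (aaNew == "*" && aaOld != "*") "NONSENSE"
  else "MISSENSE"
}

## multi-nucleotide substitution (equal allele lengths > 1); used for
## merged dinucleotide events.  Splice precedence as for indels.
classifyMnv <- function(model, pos, ref, alt) {
  len <- nchar(ref)
  span <- pos:(pos + len - 1L)
  if (any(vapply(span, isSpliceSite, TRUE, model = model)))
    return("SPLICE_SITE")
  coding <- vapply(span, .inCoding, TRUE, model = model)
  if (!any(coding)) return("NONCODING_OTHER")
  cds <- cdsSequence(model)
  newCds <- cds
  L <- nchar(model@sequence)
  for (k in seq_len(len)) {
    if (!coding[k]) next
    off <- .checkRef(model, span[k], substr(ref, k, k))
    a <- substr(alt, k, k)
    if (model@strand == "+") {
      cdsPos <- off; ca <- a
    } else {
      cdsPos <- L - off + 1L; ca <- unname(.COMP[a])
    }
    substr(newCds, cdsPos, cdsPos) <- ca
  }
  gc <- .geneticCode()
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  aaOld <- unname(gc[codons(cds)]); aaNew <- unname(gc[codons(newCds)])
  if (any(aaNew == "*" & aaOld != "*")) "NONSENSE"
  else if (any(aaNew != aaOld)) "MISSENSE"
  else "SILENT"
}

#' Classify an insertion or deletion
#'
#' Indels whose affected span touches a splice window or crosses an
#' exon/intron boundary classify as `SPLICE_SITE`; indels entirely
#' outside coding territory are `NONCODING_OTHER`; otherwise the length
#' difference modulo 3 decides `FRAMESHIFT_INDEL` vs `IN_FRAME_INDEL`.
#' Alleles follow the table convention: empty `alt` with non-empty
#' `ref` is a pure deletion; `ref` shorter than `alt` is an insertion.
#'
#' @param model a [TranscriptModel].
#' @param pos genomic position of the first affected base.
#' @param ref,alt allele strings of unequal length.
#' @return one of [CONSEQUENCE_CLASSES].
#' @export
classifyIndel <- function(model, pos, ref, alt) {
  if (nchar(ref) == nchar(alt))
    stop("classifyIndel requires alleles of unequal length")
  span <- pos:(pos + max(nchar(ref), 1L) - 1L)
  if (any(vapply(span, isSpliceSite, TRUE, model = model)))
    return("SPLICE_SITE")
  coding <- vapply(span, .inCoding, TRUE, model = model)
  if (!any(coding)) return("NONCODING_OTHER")
  if (!all(coding)) return("SPLICE_SITE")  # spans an exon boundary
  if (abs(nchar(ref) - nchar(alt)) %% 3L != 0L) "FRAMESHIFT_INDEL"
  else "IN_FRAME_INDEL"
}

#' Classify consequences for a table of events
#'
#' Driver dispatching each event (single variants or merged dinucleotide
#' events) to [classifySnv()], `classifyMnv` or [classifyIndel()] using
#' the transcript model matching its gene.
#'
#' @param events data.frame with gene, pos, ref, alt columns.
#' @param models named list of [TranscriptModel] keyed by gene.
#' @return character vector of consequence classes.
#' @export
classifyConsequence <- function(events, models) {
  missing <- setdiff(unique(events$gene), names(models))
  if (length(missing))
    stop("no transcript model for gene(s): ",
         paste(missing, collapse = ", "))
  vapply(seq_len(nrow(events)), function(i) {
    m <- models[[events$gene[i]]]
    ref <- events$ref[i]; alt <- events$alt[i]
    if (nchar(ref) != nchar(alt))
      classifyIndel(m, events$pos[i], ref, alt)
    else if (nchar(ref) == 1L)
      classifySnv(m, events$pos[i], ref, alt)
    else
      classifyMnv(m, events$pos[i], ref, alt)
  }, character(1))
}
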