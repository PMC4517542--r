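# Shared fixtures and independent oracles, all built in code.

# single-exon toy model on a chosen strand; CDS given 5'->3'
toyModel <- function(cds, strand = "+", start = 101L, gene = "TOY",
                     chrom = "ctg_TOY", spliceWindow = 2L) {
  plusSeq <- if (strand == "+") cds else revcompStr(cds)
  TranscriptModel(gene = gene, chrom = chrom, strand = strand,
                  starts = start, ends = start + nchar(cds) - 1L,
                  sequence = plusSeq, spliceWindow = spliceWindow)
}

revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# multi-exon toy model from a deterministic seed, mirroring realistic
# gene structure (ATG start, no internal stop, TAA end)
randomToyModel <- function(seed, nCodons = 40L, nExons = 3L,
                           strand = "+", gene = "TOY") {
  withr::with_seed(seed, {
    codons <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))
    cds <- paste0("ATG", paste(sample(codons, nCodons - 2L,
                                      replace = TRUE), collapse = ""),
                  "TAA")
    L <- nchar(cds)
    plusSeq <- if (strand == "+") cds else revcompStr(cds)
    cuts <- sort(sample(10:(L - 10), nExons - 1L))
    lens <- diff(c(0L, cuts, L))
    starts <- integer(nExons); ends <- integer(nExons)
    pos <- 501L
    for (i in seq_len(nExons)) {
      starts[i] <- pos
      ends[i] <- pos + lens[i] - 1L
      pos <- ends[i] + 101L
    }
    TranscriptModel(gene = gene, chrom = paste0("ctg_", gene),
                    strand = strand, starts = starts, ends = ends,
                    sequence = plusSeq)
  })
}

# Independent consequence oracle: re-translate the whole coding sequence
# before and after a single-base substitution (Biostrings translation).
oracleSnvClass <- function(model, pos, alt) {
  s <- model@starts; e <- model@ends
  gpos <- unlist(mapply(seq.int, s, e, SIMPLIFY = FALSE))
  off <- match(pos, gpos)
  plusSeq <- model@sequence
  newPlus <- plusSeq
  substr(newPlus, off, off) <- alt
  cdsOf <- function(x) if (model@strand == "+") x else revcompStr(x)
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(cdsOf(x)), no.init.codon = TRUE))
  aaOld <- strsplit(tr(plusSeq), "")[[1]]
  aaNew <- strsplit(tr(newPlus), "")[[1]]
  if (any(aaNew == "*" & aaOld != "*")) "NONSENSE"
  else if (any(aaNew != aaOld)) "MISSENSE"
  else "SILENT"
}

# minimal variant table builder
makeVariants <- function(sample_id, chrom, pos, ref, alt, gene,
                         allele_fraction = NA_real_,
                         site_coverage = NA_real_) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene,
             allele_fraction = allele_fraction,
             site_coverage = site_coverage, stringsAsFactors = FALSE)
}

# small annotated event table for cohort tallies
makeEvents <- function(sample_id, gene, consequence = "MISSENSE",
                       uv_class = "UVB_SINGLE_C_TO_T") {
  data.frame(sample_id = sample_id, gene = gene,
             consequence = consequence, uv_class = uv_class,
             stringsAsFactors = FALSE)
}

# shared small simulated cohort (models reused across tests for speed)
sharedSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateCohort(SimConfig(seed = 4242))
    cache
  }
})
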