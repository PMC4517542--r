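## Seeded synthetic-cohort generator with ground-truth labels.
## Per-sample mutation counts are negative-binomial (heavy-tailed, SD
## about equal to the mean at default settings), genes receive Zipf-like
## weights with epigenetic genes multiplied by a configurable rate
## factor, and each event is drawn from a UVB-dominated process mixture
## and placed on a toy transcript so the consequence and UV classifiers
## can recover the truth.

## sample() that never falls into the 1:n trap on length-1 vectors
.sampleVec <- function(x, n = length(x)) x[sample.int(length(x), n)]

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.simRegistry <- function(nEpigenetic) {
  reg <- defaultRegistry()
  ent <- reg@entries
  if (nEpigenetic <= length(ent)) return(EpigeneticRegistry(ent[seq_len(nEpigenetic)]))
  extra <- nEpigenetic - length(ent)
  more <- setNames(rep("HISTONE_MODIFICATION", extra),
                   sprintf("EPI_X%02d", seq_len(extra)))
  EpigeneticRegistry(c(ent, more))
}

.simPanel <- function(panelSize, registry) {
  core <- c("BRAF", "NRAS", "TP53", "CDKN2A", "NF1")
  genes <- unique(c(core, registryGenes(registry)))
  fill <- panelSize - length(genes)
  if (fill < 0) stop("panelSize too small for the registry")
  genes <- c(genes, sprintf("GENE%03d", seq_len(fill)))
  PanelDefinition(genes)
}

## Deterministic rank assignment.  A handful of recurrently mutated
## melanoma genes take the top ranks (MECOM and KMT2D epigenetic among
## them); the remaining epigenetic ranks are chosen by a greedy that
## balances mean epigenetic vs non-epigenetic Zipf weight, so that a
## rate multiplier of 1 yields per-gene rates with enrichment ~ 1.
.assignRanks <- function(genes, epiGenes, zipfExponent) {
  n <- length(genes)
  w <- (seq_len(n))^(-zipfExponent)
  fixedEpi <- intersect(c("MECOM", "KMT2D"), epiGenes)
  fixedEpiRank <- c(MECOM = 2L, KMT2D = 5L)[fixedEpi]
  fixedNon <- intersect(c("BRAF", "NRAS", "TP53", "CDKN2A", "NF1"),
                        setdiff(genes, epiGenes))
  fixedNonRank <- c(BRAF = 1L, NRAS = 3L, TP53 = 4L, CDKN2A = 6L,
                    NF1 = 7L)[fixedNon]

  k <- length(epiGenes)
  target <- mean(w) * k
  picks <- as.integer(fixedEpiRank)
  acc <- sum(w[picks])
  avail <- setdiff(seq_len(n), c(picks, fixedNonRank))
  nLeft <- k - length(picks)
  for (i in seq_len(nLeft)) {
    need <- (target - acc) / (nLeft - i + 1)
    j <- avail[which.min(abs(w[avail] - need))]
    picks <- c(picks, j)
    acc <- acc + w[j]
    avail <- setdiff(avail, j)
  }
  epiRanks <- sort(picks)
  epiRanks <- c(as.integer(fixedEpiRank),
                setdiff(epiRanks, as.integer(fixedEpiRank)))

  rank <- integer(n)
  names(rank) <- genes
  rank[fixedEpi] <- as.integer(fixedEpiRank)
  rank[fixedNon] <- as.integer(fixedNonRank)
  restEpi <- setdiff(epiGenes, fixedEpi)
  rank[restEpi] <- setdiff(epiRanks, as.integer(fixedEpiRank))[
    seq_along(restEpi)]
  restGenes <- setdiff(genes, c(fixedEpi, fixedNon, restEpi))
  rank[restGenes] <- setdiff(seq_len(n), rank[rank > 0])
  data.frame(gene = genes, rank = unname(rank[genes]),
             weight = w[rank[genes]],
             isEpigenetic = genes %in% epiGenes,
             stringsAsFactors = FALSE)
}

## random toy transcript: 100-180 codons, 2-3 exons, introns of 200 nt,
## ATG start, no premature stop, TAA stop; random strand.
.simModel <- function(gene) {
  nCod <- sample(100:180, 1L)
  codons <- setdiff(names(Biostrings::GENETIC_CODE), .STOP_CODONS)
  cds <- paste0("ATG", paste(sample(codons, nCod - 2L, replace = TRUE),
                             collapse = ""), "TAA")
  L <- nchar(cds)
  strand <- sample(c("+", "-"), 1L)
  plusSeq <- if (strand == "+") cds else .revcomp(cds)
  nEx <- sample(2:3, 1L)
  cuts <- sort(sample(20:(L - 20), nEx - 1L))
  lens <- diff(c(0L, cuts, L))
  starts <- integer(nEx); ends <- integer(nEx)
  pos <- 1001L
  for (i in seq_len(nEx)) {
    starts[i] <- pos
    ends[i] <- pos + lens[i] - 1L
    pos <- ends[i] + 201L  # 200 nt intron
  }
  TranscriptModel(gene = gene, chrom = paste0("ctg_", gene),
                  strand = strand, starts = starts, ends = ends,
                  sequence = plusSeq)
}

## Vectorized enumeration of all non-silent single-base substitutions
## plus the auxiliary candidate sets the event placer needs.
.simCandidates <- function(model) {
  s <- model@starts; e <- model@ends
  gpos <- unlist(mapply(seq.int, s, e, SIMPLIFY = FALSE))
  L <- length(gpos)
  plusBase <- strsplit(model@sequence, "")[[1]]
  cdsPos <- if (model@strand == "+") seq_len(L) else L - seq_len(L) + 1L
  cds <- cdsSequence(model)
  within <- (cdsPos - 1L) %% 3L + 1L
  codonStart <- cdsPos - within + 1L
  codon <- substring(cds, codonStart, codonStart + 2L)
  gc <- .geneticCode()
  aaOld <- unname(gc[codon])

  subList <- list()
  for (refB in c("A", "C", "G", "T")) {
    sel <- which(plusBase == refB)
    if (!length(sel)) next
    for (altB in setdiff(c("A", "C", "G", "T"), refB)) {
      calt <- if (model@strand == "+") altB else unname(.COMP[altB])
      newCodon <- paste0(substring(codon[sel], 1L, within[sel] - 1L), calt,
                         substring(codon[sel], within[sel] + 1L, 3L))
      aaNew <- unname(gc[newCodon])
      ns <- aaNew != aaOld[sel]
      if (!any(ns)) next
      subList[[length(subList) + 1L]] <- data.frame(
        pos = gpos[sel][ns], ref = refB, alt = altB,
        cons = ifelse(aaNew[ns] == "*" & aaOld[sel][ns] != "*",
                      "NONSENSE", "MISSENSE"),
        stringsAsFactors = FALSE)
    }
  }
  sub <- do.call(rbind, subList)

  ## adjacent coding pairs (same exon)
  adj <- gpos[-L][gpos[-1L] == gpos[-L] + 1L]
  base <- setNames(plusBase, gpos)
  ccLeft <- adj[base[as.character(adj)] == "C" &
                  base[as.character(adj + 1L)] == "C"]
  ccOk <- character(0)
  if (length(ccLeft)) {
    cons <- vapply(ccLeft, function(p)
      classifyMnv(model, p, "CC", "TT"), "")
    ccOk <- data.frame(pos = ccLeft[cons %in% NON_SILENT_CLASSES],
                       cons = cons[cons %in% NON_SILENT_CLASSES])
  } else ccOk <- data.frame(pos = integer(0), cons = character(0))
  cLeft <- adj[base[as.character(adj)] == "C"]

  ## splice-window positions around internal boundaries
  w <- model@spliceWindow; nEx <- length(s)
  spl <- integer(0)
  if (nEx > 1L && w > 0L) {
    for (i in seq_len(nEx - 1L))
      spl <- c(spl, (e[i] + 1L):(e[i] + w), (s[i + 1L] - w):(s[i + 1L] - 1L))
  }

  ## interior positions safe for deletions up to 3 nt
  interior <- unlist(mapply(function(a, b) if (b - 5L >= a + 3L)
    seq.int(a + 3L, b - 5L) else integer(0), s, e, SIMPLIFY = FALSE))

  list(sub = sub, ct = sub[sub$ref == "C" & sub$alt == "T", ],
       gt = sub[sub$ref == "G" & sub$alt == "T", ],
       other = sub[!(sub$ref == "C" & sub$alt == "T") &
                     !(sub$ref == "G" & sub$alt == "T"), ],
       ccPairs = ccOk, cPairs = cLeft, base = base, spl = spl,
       interior = interior, offset = setNames(seq_len(L), gpos))
}

#' Simulate a targeted-panel mutation cohort
#'
#' Generates a full synthetic cohort: per-sample mutation counts from a
#' negative binomial, genes drawn with Zipf-like weights (epigenetic
#' genes at `epigeneticRateMultiplier` times their base rate), event
#' classes from the configured UV-process mixture, and coordinates and
#' alleles placed on generated toy transcripts such that the consequence
#' and UV classifiers recover the intended labels.  Dinucleotide events
#' are emitted as two adjacent single-base rows (to be re-merged by
#' [mergeAdjacentSnvs()]); all events are non-silent.  Fully
#' deterministic given the seed (the caller's RNG state is preserved).
#'
#' @param cfg a [SimConfig].
#' @param models optional named list of [TranscriptModel] to reuse
#'   (e.g. across replicates); generated from the seed when NULL.
#' @param clinicalAssociation optional list(target=, breslowShiftSd=):
#'   shifts the Breslow depth of mutated primary samples by the given
#'   number of Breslow SDs, for power testing; by default the clinical
#'   table is independent of the mutations (null scenario).
#' @return list with elements `variants` (mutation table rows),
#'   `models`, `registry`, `panel`, `clinical`, `truth` (per-event true
#'   classes, realized mixture, per-gene rates) and `config`.
#' @export
simulateCohort <- function(cfg, models = NULL, clinicalAssociation = NULL) {
  validObject(cfg)
  .withSeed(cfg@seed, {
    registry <- .simRegistry(cfg@nEpigenetic)
    panel <- .simPanel(cfg@panelSize, registry)
    genes <- panelGenes(panel)
    ranks <- .assignRanks(genes, registryGenes(registry), cfg@zipfExponent)
    prob <- ranks$weight *
      ifelse(ranks$isEpigenetic, cfg@epigeneticRateMultiplier, 1)
    prob <- prob / sum(prob)
    ranks$prob <- prob

    if (is.null(models)) {
      models <- lapply(genes, .simModel)
      names(models) <- genes
    }
    ## candidate tables are deterministic per model; cache them on the
    ## models list so replicate runs that reuse models skip the scan
    cand <- attr(models, "simCandidates")
    if (is.null(cand)) {
      cand <- lapply(models, .simCandidates)
      attr(models, "simCandidates") <- cand
    }

    mixture <- c(uvb_single = cfg@uvbSingleFrac, cc_tt = cfg@uvbCcTtFrac,
                 dinuc = cfg@uvbDinucFrac, uva = cfg@uvaFrac,
                 indel = cfg@indelFrac, splice = cfg@spliceFrac)
    mixture <- c(mixture, other = 1 - sum(mixture))

    sampleIds <- sprintf("S%03d", seq_len(cfg@nSamples))
    nMut <- pmax(1L, rnbinom(cfg@nSamples, size = cfg@dispersion,
                             mu = cfg@meanMutationsPerSample))

    used <- new.env(parent = emptyenv())
    okDist <- function(key, ps) {
      u <- used[[key]]
      is.null(u) || all(vapply(ps, function(p) min(abs(u - p)) >= 2L, TRUE))
    }
    markUsed <- function(key, ps) used[[key]] <- c(used[[key]], ps)

    varRows <- list(); truthRows <- list(); vi <- 0L; ti <- 0L
    addVar <- function(sid, model, pos, ref, alt, af, cov) {
      vi <<- vi + 1L
      varRows[[vi]] <<- data.frame(
        sample_id = sid, chrom = model@chrom, pos = pos, ref = ref,
        alt = alt, gene = model@gene, allele_fraction = af,
        site_coverage = cov, stringsAsFactors = FALSE)
    }
    addTruth <- function(sid, model, pos, ref, alt, cons, uv, nComp, cls) {
      ti <<- ti + 1L
      truthRows[[ti]] <<- data.frame(
        sample_id = sid, gene = model@gene, chrom = model@chrom,
        pos = pos, ref = ref, alt = alt, true_consequence = cons,
        true_uv = uv, n_components = nComp, class_drawn = cls,
        stringsAsFactors = FALSE)
    }

    placeEvent <- function(sid, gene, cls) {
      m <- models[[gene]]; cd <- cand[[gene]]
      key <- paste(sid, gene)
      af <- round(stats::rbeta(1, 8, 12), 3)
      cov <- 100L + rnbinom(1L, size = 10, mu = 150)
      pickRow <- function(df) {
        if (!nrow(df)) return(NULL)
        ok <- vapply(df$pos, function(p) okDist(key, p), TRUE)
        if (!any(ok)) return(NULL)
        df[.sampleVec(which(ok), 1L), , drop = FALSE]
      }
      if (cls %in% c("uvb_single", "uva", "other")) {
        df <- switch(cls, uvb_single = cd$ct, uva = cd$gt, other = cd$other)
        r <- pickRow(df)
        if (is.null(r)) return(FALSE)
        markUsed(key, r$pos)
        addVar(sid, m, r$pos, r$ref, r$alt, af, cov)
        uv <- switch(cls, uvb_single = "UVB_SINGLE_C_TO_T",
                     uva = "UVA_G_TO_T", other = "OTHER")
        addTruth(sid, m, r$pos, r$ref, r$alt, r$cons, uv, 1L, cls)
        return(TRUE)
      }
      if (cls == "cc_tt") {
        df <- cd$ccPairs
        if (!nrow(df)) return(FALSE)
        ok <- vapply(df$pos, function(p) okDist(key, c(p, p + 1L)), TRUE)
        if (!any(ok)) return(FALSE)
        r <- df[.sampleVec(which(ok), 1L), , drop = FALSE]
        markUsed(key, c(r$pos, r$pos + 1L))
        addVar(sid, m, r$pos, "C", "T", af, cov)
        addVar(sid, m, r$pos + 1L, "C", "T", af, cov)
        addTruth(sid, m, r$pos, "CC", "TT", r$cons, "UVB_CC_TO_TT", 2L,
                 cls)
        return(TRUE)
      }
      if (cls == "dinuc") {
        ps <- cd$cPairs
        ps <- ps[vapply(ps, function(p) okDist(key, c(p, p + 1L)), TRUE)]
        if (!length(ps)) return(FALSE)
        for (p in .sampleVec(ps, min(8L, length(ps)))) {
          ref2 <- unname(cd$base[as.character(p + 1L)])
          alts2 <- setdiff(c("A", "C", "G", "T"), ref2)
          if (ref2 == "C") alts2 <- setdiff(alts2, "T")  # avoid CC>TT
          for (a2 in .sampleVec(alts2)) {
            cons <- classifyMnv(m, p, paste0("C", ref2), paste0("T", a2))
            if (cons %in% NON_SILENT_CLASSES) {
              markUsed(key, c(p, p + 1L))
              addVar(sid, m, p, "C", "T", af, cov)
              addVar(sid, m, p + 1L, ref2, a2, af, cov)
              addTruth(sid, m, p, paste0("C", ref2), paste0("T", a2),
                       cons, "UVB_C_TO_T_IN_DINUCLEOTIDE", 2L, cls)
              return(TRUE)
            }
          }
        }
        return(FALSE)
      }
      if (cls == "splice") {
        ps <- cd$spl[vapply(cd$spl, function(p) okDist(key, p), TRUE)]
        if (!length(ps)) return(FALSE)
        p <- .sampleVec(ps, 1L)
        markUsed(key, p)
        addVar(sid, m, p, "G", "A", af, cov)
        addTruth(sid, m, p, "G", "A", "SPLICE_SITE", "OTHER", 1L, cls)
        return(TRUE)
      }
      if (cls == "indel") {
        len <- if (runif(1) < 0.8) 1L else 3L
        ps <- cd$interior[vapply(cd$interior, function(p)
          okDist(key, seq.int(p - 1L, p + len)), TRUE)]
        if (!length(ps)) return(FALSE)
        p <- .sampleVec(ps, 1L)
        off <- cd$offset[[as.character(p)]]
        ref <- substr(m@sequence, off, off + len - 1L)
        markUsed(key, seq.int(p, p + len - 1L))
        addVar(sid, m, p, ref, "", af, cov)
        cons <- if (len %% 3L) "FRAMESHIFT_INDEL" else "IN_FRAME_INDEL"
        addTruth(sid, m, p, ref, "", cons, "OTHER", 1L, "indel")
        return(TRUE)
      }
      FALSE
    }

    for (si in seq_len(cfg@nSamples)) {
      classes <- sample(names(mixture), nMut[si], replace = TRUE,
                        prob = mixture)
      for (cls in classes) {
        placed <- FALSE
        for (try in 1:100) {
          gene <- sample(genes, 1L, prob = prob)
          if (placeEvent(sampleIds[si], gene, cls)) { placed <- TRUE; break }
        }
        if (!placed)
          stop("could not place a '", cls, "' event after 100 attempts")
      }
    }

    variants <- do.call(rbind, varRows)
    truth <- do.call(rbind, truthRows)
    rownames(variants) <- rownames(truth) <- NULL

    clinical <- .simClinical(sampleIds, truth, registry,
                             clinicalAssociation)
    realized <- table(factor(truth$class_drawn, levels = names(mixture)))
    list(variants = variants, models = models, registry = registry,
         panel = panel, clinical = clinical,
         truth = list(events = truth,
                      realizedMixture = as.numeric(realized) /
                        sum(realized),
                      mixtureNames = names(mixture),
                      geneRates = ranks),
         config = cfg)
  })
}

.simClinical <- function(sampleIds, truth, registry, assoc = NULL) {
  n <- length(sampleIds)
  nPrim <- max(1L, round(n * 13 / 38))
  cls <- c(rep("primary", nPrim), rep("metastasis", n - nPrim))
  breslow <- round(pmax(0.4, rnorm(n, 3.66, 1.94)), 2)
  mitotic <- pmax(1L, as.integer(round(rnorm(n, 5.3, 4.5))))
  ulcer <- rbinom(n, 1L, 6 / 13) == 1L
  sites <- sample(c("lymph_node", "thorax", "abdomen", "cns",
                    "subcutaneous"), n, replace = TRUE,
                  prob = c(0.44, 0.16, 0.16, 0.12, 0.12))
  df <- data.frame(
    sample_id = sampleIds, specimen_class = cls,
    breslow_mm = ifelse(cls == "primary", breslow, NA_real_),
    mitotic_rate_per_mm2 = ifelse(cls == "primary", mitotic, NA_integer_),
    ulceration = ifelse(cls == "primary", ulcer, NA),
    metastatic_site = ifelse(cls == "metastasis", sites, NA_character_),
    age_years = pmin(83L, pmax(21L, as.integer(round(rnorm(n, 60.9,
                                                           13.06))))),
    stringsAsFactors = FALSE)
  if (!is.null(assoc)) {
    target <- assoc$target
    mutSamples <- if (target %in% EPIGENETIC_CATEGORIES) {
      cat <- registryCategory(registry, truth$gene)
      unique(truth$sample_id[!is.na(cat) & cat == target])
    } else unique(truth$sample_id[truth$gene == toupper(target)])
    hit <- df$specimen_class == "primary" & df$sample_id %in% mutSamples
    df$breslow_mm[hit] <- df$breslow_mm[hit] +
      assoc$breslowShiftSd * 1.94
  }
  df
}

#' Write a simulated cohort to disk
#'
#' Emits the exact file dialects the readers consume: mutation table,
#' transcript model TSV + FASTA, registry TSV, clinical TSV and
#' ground-truth TSV.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, named character vector of the files written.
#' @export
writeSimulatedCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeMutationTable(sim$variants, p("mutations.tsv"))
  writeTranscriptModels(sim$models, p("transcript_models.tsv"),
                        p("transcript_seqs.fa"))
  reg <- data.frame(gene = registryGenes(sim$registry),
                    category = unname(sim$registry@entries))
  write.table(reg, p("registry.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = panelGenes(sim$panel)), p("panel.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$clinical, p("clinical.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(sim$truth$events, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(mutations = p("mutations.tsv"),
              models = p("transcript_models.tsv"),
              sequences = p("transcript_seqs.fa"),
              registry = p("registry.tsv"), panel = p("panel.tsv"),
              clinical = p("clinical.tsv"), truth = p("truth.tsv")))
}

#' Recover simulation parameters from a classified event table
#'
#' Plug-in estimates of the process mixture (class proportions over all
#' classified events) and of the epigenetic rate enrichment, defined as
#' mutations per epigenetic gene divided by mutations per
#' non-epigenetic gene.
#'
#' @param events annotated event data.frame with `uv_class` and `gene`.
#' @param registry an [EpigeneticRegistry].
#' @param panel a [PanelDefinition].
#' @return list(uvb_single_frac, uvb_cc_tt_frac, uvb_dinuc_frac,
#'   uva_frac, other_frac, enrichment, nEvents).
#' @export
recoverParameters <- function(events, registry, panel) {
  if (!nrow(events)) stop("empty event table")
  n <- nrow(events)
  tab <- table(factor(events$uv_class, levels = UV_CLASSES))
  nEpiGenes <- length(intersect(panelGenes(panel), registryGenes(registry)))
  nNonGenes <- length(panel) - nEpiGenes
  epiEvents <- sum(events$gene %in% registryGenes(registry))
  list(uvb_single_frac = unname(tab[["UVB_SINGLE_C_TO_T"]] / n),
       uvb_cc_tt_frac = unname(tab[["UVB_CC_TO_TT"]] / n),
       uvb_dinuc_frac = unname(tab[["UVB_C_TO_T_IN_DINUCLEOTIDE"]] / n),
       uva_frac = unname(tab[["UVA_G_TO_T"]] / n),
       other_frac = unname(tab[["OTHER"]] / n),
       enrichment = (epiEvents / nEpiGenes) /
         ((n - epiEvents) / nNonGenes),
       nEvents = n)
}
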