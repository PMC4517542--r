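test_that("mutation table parsing handles empty input and identity rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample\tchrom\tpos\tref\talt\tgene", f)
  res <- readMutationTable(f)
  expect_equal(nrow(res$variants), 0)
  expect_equal(nrow(res$rejects), 0)

  writeLines(c("sample\tchrom\tpos\tref\talt\tgene",
               "S1\t7\t140453136\tA\tT\tBRAF"), f)
  res <- readMutationTable(f)
  expect_equal(nrow(res$variants), 1)
  expect_equal(res$variants$pos, 140453136L)
  expect_equal(res$variants$gene, "BRAF")
  expect_true(is.na(res$variants$allele_fraction))
})

test_that("missing mandatory column is a hard error naming the column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tpos\tref\tgene", "S1\t1\t5\tA\tX"), f)
  expect_error(readMutationTable(f), "alt")
})

test_that("invalid rows are rejected with reasons, never dropped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tpos\tref\talt\tgene",
               "S1\t1\t100\tC\tT\tBRAF",
               "S1\t1\tnot_a_number\tC\tT\tBRAF",
               "S1\t1\t100\tC\tC\tBRAF",
               "S1\t1\t100\tN\tT\tBRAF",
               "S1\t1\t100\tC\tT\tNOT_IN_PANEL"), f)
  panel <- PanelDefinition(c("BRAF", "NRAS"))
  res <- readMutationTable(f, panel = panel)
  expect_equal(nrow(res$variants) + nrow(res$rejects), 5)
  expect_equal(nrow(res$variants), 1)
  expect_setequal(res$rejects$reason,
                  c("unparseable_position", "ref_equals_alt",
                    "non_acgt_allele", "gene_not_in_panel"))
})

test_that("write then read round-trips simulated variants field by field", {
  sim <- sharedSim()
  v <- sim$variants[1:50, ]
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMutationTable(v, f)
  back <- readMutationTable(f)
  expect_equal(nrow(back$rejects), 0)
  rownames(v) <- NULL
  expect_equal(back$variants, v, tolerance = 1e-12)
  # byte-level round trip of the canonical dialect
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeMutationTable(back$variants, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("gene aliases normalize to canonical symbols", {
  expect_equal(normalizeGeneSymbols(c("MLL2", "mll", "EVI1", "BRAF")),
               c("KMT2D", "KMT2A", "MECOM", "BRAF"))
})

test_that("minimal VCF reading splits multi-allelic records and matches the table dialect", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "ctg1\t100\t.\tC\tT\t.\t.\tGENE=BRAF;DP=120;AF=0.31",
    "ctg1\t200\t.\tA\tT,G\t.\t.\tGENE=NRAS;DP=80;AF=0.2,0.1",
    "ctg1\t300\t.\tG\tA\t.\t.\tDP=99"), vcf)
  res <- readVcfMinimal(vcf)
  expect_equal(nrow(res$variants), 3)  # biallelic + split multi-allelic
  expect_equal(nrow(res$rejects), 1)
  expect_equal(res$rejects$reason, "missing_gene_annotation")
  ma <- res$variants[res$variants$gene == "NRAS", ]
  expect_equal(nrow(ma), 2)
  expect_equal(unique(ma$pos), 200L)
  expect_equal(unique(ma$ref), "A")
  expect_setequal(ma$alt, c("T", "G"))

  # equivalent mutation table gives an identical variant sequence
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeMutationTable(res$variants, tsv)
  again <- readMutationTable(tsv)
  expect_equal(again$variants, res$variants, tolerance = 1e-9)
})

test_that("registry reading validates the four-category taxonomy", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcategory", "TET2\tDNA_METHYLATION_DEMETHYLATION"), f)
  reg <- readEpigeneticRegistry(f)
  expect_equal(length(reg), 1)
  expect_equal(registryCategory(reg, "TET2"),
               "DNA_METHYLATION_DEMETHYLATION")

  writeLines("gene\tcategory", f)
  expect_equal(length(readEpigeneticRegistry(f)), 0)

  writeLines(c("gene\tcategory", "TET2\tNOT_A_CATEGORY"), f)
  expect_error(readEpigeneticRegistry(f), "unknown category")

  writeLines(c("gene\tcategory", "TET2\tHISTONE_MODIFICATION",
               "TET2\tCHROMATIN_REMODELING"), f)
  expect_error(readEpigeneticRegistry(f), "duplicate")
})

test_that("shipped default registry has 41 genes across the four categories", {
  reg <- defaultRegistry()
  expect_equal(length(reg), 41)
  tab <- table(reg@entries)
  expect_setequal(names(tab), EPIGENETIC_CATEGORIES)
  expect_equal(registryCategory(reg, "MECOM"), "HISTONE_MODIFICATION")
  expect_equal(registryCategory(reg, "ARID2"), "CHROMATIN_REMODELING")
})

test_that("panel reading converts BED to 1-based inclusive coordinates", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("ctg1\t99\t200\tBRAF", "ctg1\t300\t400\tMLL2"), bed)
  panel <- readPanel(bed)
  expect_setequal(panelGenes(panel), c("BRAF", "KMT2D"))
  gr <- panel@intervals
  expect_equal(GenomicRanges::start(gr), c(100L, 301L))
  expect_equal(GenomicRanges::end(gr), c(200L, 400L))
})

test_that("transcript models round-trip through TSV + FASTA", {
  sim <- sharedSim()
  models <- sim$models[1:5]
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeTranscriptModels(models, tsv, fa)
  back <- readTranscriptModels(tsv, fa)
  expect_setequal(names(back), names(models))
  for (g in names(models)) {
    expect_equal(back[[g]]@starts, models[[g]]@starts)
    expect_equal(back[[g]]@strand, models[[g]]@strand)
    expect_equal(back[[g]]@sequence, models[[g]]@sequence)
  }
})

test_that("clinical table enforces primary-only fields", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("sample_id", "specimen_class", "breslow_mm",
                     "mitotic_rate_per_mm2", "ulceration",
                     "metastatic_site", "age_years", sep = "\t"),
               "S1\tprimary\t3.1\t4\tTRUE\t\t62",
               "S2\tmetastasis\t\t\t\tlymph_node\t70"), f)
  cl <- readClinicalTable(f)
  expect_equal(nrow(cl), 2)
  expect_true(is.na(cl$breslow_mm[2]))

  writeLines(c(paste("sample_id", "specimen_class", "breslow_mm",
                     "mitotic_rate_per_mm2", "ulceration",
                     "metastatic_site", "age_years", sep = "\t"),
               "S2\tmetastasis\t2.2\t\t\tlymph_node\t70"), f)
  expect_error(readClinicalTable(f), "S2")
})
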