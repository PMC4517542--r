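# 12-event, 3-sample fixture with hand-counted tallies
fixtureEvents <- function() {
  makeEvents(
    sample_id = c("S1", "S1", "S1", "S1", "S2", "S2", "S2", "S2",
                  "S3", "S3", "S3", "S3"),
    gene = c("E1", "E1", "B1", "B2", "E2", "B1", "B1", "B3",
             "B2", "B2", "E1", "B1"),
    consequence = c("MISSENSE", "NONSENSE", "MISSENSE", "MISSENSE",
                    "MISSENSE", "NONSENSE", "MISSENSE", "SPLICE_SITE",
                    "MISSENSE", "FRAMESHIFT_INDEL", "MISSENSE",
                    "MISSENSE"),
    uv_class = c("UVB_SINGLE_C_TO_T", "OTHER", "UVB_CC_TO_TT", "OTHER",
                 "UVB_SINGLE_C_TO_T", "UVB_SINGLE_C_TO_T", "OTHER",
                 "OTHER", "UVB_SINGLE_C_TO_T", "OTHER",
                 "UVB_C_TO_T_IN_DINUCLEOTIDE", "UVB_SINGLE_C_TO_T"))
}
fixtureRegistry <- function() {
  EpigeneticRegistry(c(E1 = "HISTONE_MODIFICATION",
                       E2 = "CHROMATIN_REMODELING"))
}
fixturePanel <- function() PanelDefinition(c("E1", "E2", "B1", "B2", "B3"))

test_that("cohort tallies equal hand counts on the fixture", {
  s <- summarizeCohort(fixtureEvents(), fixtureRegistry(), fixturePanel(),
                       nSamples = 4)
  pg <- perGene(s)
  rownames(pg) <- pg$gene
  expect_equal(pg["E1", "totalMutations"], 3L)
  expect_equal(pg["E1", "nPatientsMutated"], 2L)
  expect_equal(pg["E1", "uvbMutations"], 2L)
  expect_equal(pg["E1", "nonsenseMutations"], 1L)
  expect_equal(pg["B1", "nPatientsMutated"], 3L)
  expect_equal(pg["B1", "uvbMutations"], 3L)
  expect_true(all(pg$nPatientsMutated <= s@nSamples))
  expect_equal(sum(pg$totalMutations), 12L)

  ps <- perSample(s)
  rownames(ps) <- ps$sampleId
  expect_equal(ps["S1", "epigeneticMutations"], 2L)
  expect_equal(ps["S3", "uvbMutations"], 3L)
  expect_equal(sum(ps$totalMutations), 12L)

  # zero-padded per-sample statistics over nSamples = 4
  expect_equal(unname(s@perSampleStats["mean"]), 3)
  expect_equal(unname(s@perSampleStats["median"]), 4)
  expect_equal(unname(s@perSampleStats["sd"]), 2)

  expect_equal(s@totals$nEvents, 12L)
  expect_equal(s@totals$nEpigeneticEvents, 4L)
  expect_equal(s@totals$nUvbEvents, 7L)
  expect_equal(unname(s@totals$byEpigeneticCategory[
    "HISTONE_MODIFICATION"]), 3L)
})

test_that("single-event cohort has mean 1 and sd 0 with one sample", {
  s <- summarizeCohort(makeEvents("S1", "B1"), fixtureRegistry(),
                       fixturePanel(), nSamples = 1)
  expect_equal(unname(s@perSampleStats["mean"]), 1)
  expect_equal(unname(s@perSampleStats["sd"]), 0)
})

test_that("summarizeCohort rejects silent events and undersized nSamples", {
  expect_error(summarizeCohort(makeEvents("S1", "B1",
                                          consequence = "SILENT"),
                               fixtureRegistry(), fixturePanel(), 1),
               "non-silent")
  expect_error(summarizeCohort(fixtureEvents(), fixtureRegistry(),
                               fixturePanel(), nSamples = 2),
               "distinct sample ids")
})

test_that("gene ranking sorts by patients, mutations, then symbol", {
  s <- summarizeCohort(fixtureEvents(), fixtureRegistry(), fixturePanel(),
                       nSamples = 4)
  r <- rankGenes(s, 10)  # n beyond the gene count: full list
  expect_equal(nrow(r), 5)
  # B1 leads on patients; B2/E1 tie on both counts -> alphabetical
  expect_equal(r$gene, c("B1", "B2", "E1", "B3", "E2"))
  expect_equal(r$isEpigenetic, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(nrow(rankGenes(s, 2)), 2)
})

test_that("epigenetic burden proportions match label counts", {
  s <- summarizeCohort(fixtureEvents(), fixtureRegistry(), fixturePanel(),
                       nSamples = 4)
  b <- epigeneticBurden(s)
  expect_equal(b$fractionOfMutations$fraction, 4 / 12)
  expect_equal(b$fractionSamplesGe1$fraction, 3 / 4)
  expect_equal(b$fractionSamplesGt1$fraction, 0)
  expect_true(b$fractionOfMutations$ciLow <= 4 / 12 &&
                4 / 12 <= b$fractionOfMutations$ciHigh)

  sNoEpi <- summarizeCohort(fixtureEvents(), EpigeneticRegistry(),
                            fixturePanel(), nSamples = 4)
  bNoEpi <- epigeneticBurden(sNoEpi)
  expect_equal(bNoEpi$fractionOfMutations$fraction, 0)
  expect_equal(bNoEpi$fractionSamplesGe1$fraction, 0)
  expect_equal(bNoEpi$fractionSamplesGt1$fraction, 0)
})

test_that("per-gene UVB distributions report mean/median/mode under both denominators", {
  # genes with UVB counts 1, 2, 3 among three mutated background genes
  ev <- makeEvents(rep("S1", 6), c("B1", "B2", "B2", "B3", "B3", "B3"))
  s <- summarizeCohort(ev, EpigeneticRegistry(), fixturePanel(), 1)
  d <- uvbPerGeneDistribution(s, "non_epigenetic", "mutated_genes")
  expect_equal(d$mean, 2)
  expect_equal(d$median, 2)
  # unmutated panel genes join as zeros under the panel denominator
  dAll <- uvbPerGeneDistribution(s, "non_epigenetic", "all_panel_genes")
  expect_equal(sort(dAll$values), c(0, 0, 1, 2, 3))
  expect_error(uvbPerGeneDistribution(s, "epigenetic", "mutated_genes"),
               "empty gene group")

  # multimodal counts {1,1,3,3} report the smallest modal value
  ev2 <- makeEvents(rep("S1", 8),
                    c("B1", "B2", "B3", "B3", "B3", "B4", "B4", "B4"))
  s2 <- summarizeCohort(ev2, EpigeneticRegistry(),
                        PanelDefinition(c("B1", "B2", "B3", "B4")), 1)
  d2 <- uvbPerGeneDistribution(s2, "non_epigenetic", "mutated_genes")
  expect_equal(sort(d2$values), c(1, 1, 3, 3))
  expect_equal(d2$mode, 1)
})

test_that("summaries are invariant under event-order permutation", {
  ev <- fixtureEvents()
  s1 <- summarizeCohort(ev, fixtureRegistry(), fixturePanel(), 4)
  set.seed(8)
  s2 <- summarizeCohort(ev[sample(nrow(ev)), ], fixtureRegistry(),
                        fixturePanel(), 4)
  expect_equal(perGene(s1), perGene(s2))
  expect_equal(perSample(s1), perSample(s2))
  expect_equal(s1@totals, s2@totals)
  expect_equal(rankGenes(s1, 5), rankGenes(s2, 5))
})

test_that("clinical association handles informative and degenerate designs", {
  clin <- data.frame(
    sample_id = sprintf("P%02d", 1:10),
    specimen_class = "primary",
    breslow_mm = c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6),
    mitotic_rate_per_mm2 = c(2, 3, 4, 5, 6, 1, 2, 3, 4, 5),
    ulceration = c(TRUE, TRUE, FALSE, FALSE, TRUE,
                   FALSE, TRUE, FALSE, TRUE, FALSE),
    metastatic_site = NA_character_, age_years = 60,
    stringsAsFactors = FALSE)
  ev <- makeEvents(sprintf("P%02d", 1:5), "E1")
  ev$epigenetic_category <- "HISTONE_MODIFICATION"
  res <- associateClinical(ev, clin, "E1")
  expect_true(isComputable(res$breslow))
  direct <- twoSampleT(clin$breslow_mm[1:5], clin$breslow_mm[6:10])
  expect_equal(pValue(res$breslow), pValue(direct))
  expect_true(isComputable(res$ulceration))
  expect_equal(attr(res, "nTests"), 3)
  # category targets route through the epigenetic annotation
  resCat <- associateClinical(ev, clin, "HISTONE_MODIFICATION")
  expect_equal(pValue(resCat$breslow), pValue(res$breslow))

  # all samples mutated: empty margin, not computable
  evAll <- makeEvents(sprintf("P%02d", 1:10), "E1")
  evAll$epigenetic_category <- "HISTONE_MODIFICATION"
  resAll <- associateClinical(evAll, clin, "E1")
  expect_false(isComputable(resAll$ulceration))
  expect_false(isComputable(resAll$breslow))
})

test_that("null clinical association p-values are roughly uniform", {
  set.seed(23)
  ps <- replicate(200, {
    clin <- data.frame(
      sample_id = sprintf("P%02d", 1:16), specimen_class = "primary",
      breslow_mm = rnorm(16, 3.5, 1.9),
      mitotic_rate_per_mm2 = rpois(16, 5),
      ulceration = runif(16) < 0.45, metastatic_site = NA_character_,
      age_years = 60, stringsAsFactors = FALSE)
    ev <- makeEvents(sample(clin$sample_id, 8), "E1")
    ev$epigenetic_category <- "HISTONE_MODIFICATION"
    pValue(associateClinical(ev, clin, "E1")$breslow)
  })
  expect_gt(mean(ps < 0.05), 0.0)   # sanity: some variation observed
  expect_lt(mean(ps < 0.05), 0.12)  # near-nominal type-I behaviour
  expect_gt(mean(ps > 0.5), 0.3)
})
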