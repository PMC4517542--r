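test_that("adjacent same-sample SNVs merge into dinucleotide events", {
  v <- makeVariants(c("S", "S"), "ctg1", c(100, 101), "C", "T", "G1",
                    allele_fraction = c(0.3, 0.5), site_coverage = c(100, 80))
  ev <- mergeAdjacentSnvs(v)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$ref, "CC")
  expect_equal(ev$alt, "TT")
  expect_equal(ev$pos, 100L)
  expect_equal(ev$n_components, 2L)
  expect_equal(ev$allele_fraction, 0.4)
  expect_equal(ev$site_coverage, 80)

  # different samples never merge
  v2 <- makeVariants(c("S", "Q"), "ctg1", c(100, 101), "C", "T", "G1")
  expect_equal(nrow(mergeAdjacentSnvs(v2)), 2)

  # non-adjacent positions never merge
  v3 <- makeVariants(c("S", "S"), "ctg1", c(100, 102), "C", "T", "G1")
  expect_equal(nrow(mergeAdjacentSnvs(v3)), 2)

  # three consecutive: leftmost pair merges, remainder single
  v4 <- makeVariants(rep("S", 3), "ctg1", 100:102, "C", "T", "G1")
  expect_message(ev4 <- mergeAdjacentSnvs(v4), "consecutive")
  expect_equal(nrow(ev4), 2)
  expect_equal(sort(ev4$n_components), c(1L, 2L))
})

test_that("merging conserves every input variant exactly once", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 40
    v <- makeVariants(sprintf("S%d", sample(3, n, TRUE)), "ctg1",
                      sample(1:60, n, TRUE), "C", "T",
                      sprintf("G%d", sample(2, n, TRUE)))
    v <- v[!duplicated(v[c("sample_id", "gene", "pos")]), ]
    ev <- mergeAdjacentSnvs(v)
    expect_equal(sum(ev$n_components), nrow(v))
  }
})

test_that("literal UV classification matches the taxonomy", {
  expect_equal(classifyUv("C", "T"), "UVB_SINGLE_C_TO_T")
  expect_equal(classifyUv("G", "T"), "UVA_G_TO_T")
  expect_equal(classifyUv("A", "G"), "OTHER")
  expect_equal(classifyUv("CC", "TT"), "UVB_CC_TO_TT")
  expect_equal(classifyUv("CA", "TG"), "UVB_C_TO_T_IN_DINUCLEOTIDE")
  expect_equal(classifyUv("AC", "GT"), "UVB_C_TO_T_IN_DINUCLEOTIDE")
  expect_equal(classifyUv("GG", "AA"), "OTHER")
  # indel and splice events always classify OTHER
  expect_equal(classifyUv("C", "T", consequence = "SPLICE_SITE"), "OTHER")
  expect_equal(classifyUv("CT", "C", consequence = "FRAMESHIFT_INDEL"),
               "OTHER")
})

test_that("pyrimidine mode strand-collapses and is complement-symmetric", {
  expect_equal(classifyUv("G", "A", mode = "pyrimidine"),
               "UVB_SINGLE_C_TO_T")
  expect_equal(classifyUv("C", "A", mode = "pyrimidine"), "UVA_G_TO_T")
  expect_equal(classifyUv("GG", "AA", mode = "pyrimidine"),
               "UVB_CC_TO_TT")

  set.seed(13)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- character(); alt <- character()
  for (i in 1:200) {
    if (runif(1) < 0.7) {
      r <- sample(bases, 1); a <- sample(setdiff(bases, r), 1)
    } else {
      r <- paste(sample(bases, 2, TRUE), collapse = "")
      repeat {
        a <- paste(sample(bases, 2, TRUE), collapse = "")
        if (substr(a, 1, 1) != substr(r, 1, 1) &&
            substr(a, 2, 2) != substr(r, 2, 2)) break
      }
    }
    ref <- c(ref, r); alt <- c(alt, a)
  }
  rcOne <- function(x) {
    if (nchar(x) == 1) comp[[x]]
    else paste0(comp[[substr(x, 2, 2)]], comp[[substr(x, 1, 1)]])
  }
  refC <- vapply(ref, rcOne, ""); altC <- vapply(alt, rcOne, "")
  t1 <- table(factor(classifyUv(ref, alt, mode = "pyrimidine"),
                     levels = UV_CLASSES))
  t2 <- table(factor(classifyUv(refC, altC, mode = "pyrimidine"),
                     levels = UV_CLASSES))
  expect_equal(as.vector(t1), as.vector(t2))
  # conservation: the five classes partition the events
  expect_equal(sum(t1), length(ref))
})

test_that("literal and pyrimidine modes agree on a C>T/CC>TT/G>T-only cohort", {
  ref <- c("C", "C", "CC", "G", "G", "C")
  alt <- c("T", "T", "TT", "T", "T", "T")
  expect_equal(classifyUv(ref, alt, mode = "literal"),
               classifyUv(ref, alt, mode = "pyrimidine"))
})

test_that("UVB fraction counts the three UVB classes with an exact CI", {
  set.seed(3)
  labels <- sample(UV_CLASSES, 200, replace = TRUE)
  fr <- uvbFraction(labels)
  expect_equal(fr$fraction, mean(labels %in% UVB_CLASSES))
  expect_equal(fr$n, 200)
  z <- uvbFraction(rep("OTHER", 10))
  expect_equal(z$fraction, 0)
  expect_equal(z$ciLow, 0)
  expect_error(uvbFraction(character(0)), "no events")
})
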