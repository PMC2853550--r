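test_that("CAI weights give every family maximum weight 1", {
  set.seed(43)
  w <- caiW(caiWeights(randomUsageTable(), CODE1))
  for (aa in setdiff(unique(CODE1), "*")) {
    fam <- ALL64[CODE1 == aa]
    expect_equal(max(w[fam]), 1)
  }
  expect_true(all(is.na(w[ALL64[CODE1 == "*"]])))
})

test_that("CAI is 1 for all-preferred genes and the weight for a constant gene", {
  vals <- stats::setNames(rep(1, 64), ALL64)
  vals[c("TTA", "TTG")] <- c(1, 4)       # w(TTA) = 0.25
  tab <- codonUsageTable(vals, scale = "counts")
  w <- caiWeights(tab, CODE1)
  expect_equal(cai("TTATTA", w), 0.25)
  expect_equal(cai("TTGTTG", w), 1)
  ## gene built only from family-maximal codons
  best <- vapply(split(ALL64[CODE1 != "*"], CODE1[CODE1 != "*"]),
                 function(fam) fam[which.max(cuValues(tab)[fam])],
                 character(1L))
  expect_equal(cai(paste(best, collapse = ""), w), 1)
})

test_that("CAI ignores codon order and single-codon families", {
  set.seed(47)
  w <- caiWeights(randomUsageTable(), CODE1)
  g <- randomGene(60)
  codons <- substring(g, seq(1, nchar(g) - 2, 3), seq(3, nchar(g), 3))
  shuffled <- paste(sample(codons), collapse = "")
  expect_equal(cai(g, w), cai(shuffled, w))
  ## appending Met/Trp codons leaves CAI unchanged
  expect_equal(cai(paste0(g, "ATGTGGATG"), w), cai(g, w))
})

test_that("zero-weight codons error without pseudo-counting", {
  vals <- stats::setNames(rep(1, 64), ALL64)
  vals["TTA"] <- 0
  w0 <- caiWeights(codonUsageTable(vals, scale = "counts"), CODE1,
                   pseudoCount = FALSE)
  expect_error(cai("TTATTA", w0), "zero weight")
  wp <- caiWeights(codonUsageTable(vals, scale = "counts"), CODE1)
  expect_equal(cai("TTATTA", wp), 0.5)   # 0.5 / family max of 1
})

test_that("ENC spans its 20-61 range at the bias extremes", {
  ## one codon per amino acid, every family observed often: maximal bias
  oneOf <- vapply(split(ALL64[CODE1 != "*"], CODE1[CODE1 != "*"]),
                  `[`, character(1L), 1L)
  gene <- paste(rep(oneOf, each = 30), collapse = "")
  expect_equal(enc(gene, CODE1), 20)

  ## exactly equal use of every synonymous codon: clipped at 61
  gene61 <- paste(rep(ALL64[CODE1 != "*"], each = 100), collapse = "")
  expect_equal(enc(gene61, CODE1), 61)

  ## uniform random synonymous sampling at n = 1e4 lands near 61
  set.seed(53)
  g <- randomGene(10000)
  expect_equal(enc(g, CODE1), 61, tolerance = 0.5 / 61)

  expect_error(enc("ATGATG", CODE1), "ENC undefined")
})

test_that("expected ENC follows Wright's curve and its symmetry", {
  expect_identical(expectedEnc(0.5), 60.5)
  expect_equal(expectedEnc(0.9), 2.9 + 29 / 0.82)
  ## the curve peaks at s = 0.5 and falls toward both extremes; the linear
  ## s term makes it slightly higher on the GC-rich side
  expect_lt(expectedEnc(0.2), expectedEnc(0.35))
  expect_lt(expectedEnc(0.8), expectedEnc(0.65))
  expect_equal(expectedEnc(0.9) - expectedEnc(0.1), 0.8)
  expect_error(expectedEnc(0), "strictly")
  expect_error(expectedEnc(1), "strictly")
})

test_that("RCDI and CAI reach their optima under different conditions", {
  set.seed(59)
  vals <- stats::setNames(stats::runif(64, 1, 100), ALL64)
  tab <- codonUsageTable(vals, scale = "counts")
  ref <- synonymousFrequencies(tab, CODE1)
  w <- caiWeights(tab, CODE1)
  ## all-preferred gene: CAI = 1 but RCDI > 1 (usage != reference mix)
  best <- vapply(split(ALL64[CODE1 != "*"], CODE1[CODE1 != "*"]),
                 function(fam) fam[which.max(vals[fam])], character(1L))
  gBest <- paste(rep(best, each = 3), collapse = "")
  expect_equal(cai(gBest, w), 1)
  expect_gt(rcdiValue(rcdi(gBest, ref)), 1 + 1e-6)
  ## matched-usage gene: RCDI = 1 but CAI < 1
  mp <- matchedPair(nFamilies = 8, maxCount = 6)
  expect_equal(rcdiValue(rcdi(mp$gene, mp$reference)), 1, tolerance = 1e-9)
  wU <- caiWeights(mp$reference, CODE1)
  expect_lt(cai(mp$gene, wU), 1)
})

test_that("codonIndices tabulates all companion indices per gene", {
  set.seed(67)
  seqs <- c(a = randomGene(500), b = randomGene(600))
  idx <- codonIndices(seqs, uniformTable(), CODE1)
  expect_equal(idx$gene_id, c("a", "b"))
  expect_true(all(idx$cai > 0 & idx$cai <= 1))
  expect_true(all(idx$enc > 20 & idx$enc <= 61))
  expect_true(all(abs(idx$expected_enc - 60.5) < 10))
})
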