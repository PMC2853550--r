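test_that("codon counting respects frame, stops and ambiguity codes", {
  cc <- countCodons("ATGTCGTCG", CODE1)
  expect_equal(cc$counts[["ATG"]], 1L)
  expect_equal(cc$counts[["TCG"]], 2L)
  expect_equal(cc$total, 3L)

  cc <- countCodons("ATGTAA", CODE1)
  expect_equal(cc$counts[["ATG"]], 1L)
  expect_equal(cc$total, 1L)
  expect_equal(countCodons("ATGTAA", CODE1, includeStops = TRUE)$total, 2L)

  cc <- countCodons("ATGNNNTCG", CODE1)
  expect_equal(cc$total, 2L)
  expect_equal(cc$excluded, 1L)

  ## internal stop detected, terminal stop not flagged as internal
  expect_equal(countCodons("ATGTAATCG", CODE1)$internalStops, 1L)
  expect_equal(countCodons("ATGTCGTAA", CODE1)$internalStops, 0L)
})

test_that("synonymous frequencies normalize within each family", {
  ## Leu family by hand: TTA 1, TTG 3, others 0 -> 0.25 / 0.75
  counts <- stats::setNames(numeric(64), ALL64)
  counts[c("TTA", "TTG")] <- c(1, 3)
  counts["ATG"] <- 5
  ft <- synonymousFrequencies(counts, CODE1)
  expect_equal(synFreq(ft)[["TTA"]], 0.25)
  expect_equal(synFreq(ft)[["TTG"]], 0.75)
  ## single-codon family is exactly 1
  expect_identical(synFreq(ft)[["ATG"]], 1)
  ## untouched families are undefined (NaN), not zero
  expect_true(is.nan(synFreq(ft)[["GGG"]]))
  ## defined families sum to 1
  f <- synFreq(ft)
  leu <- ALL64[CODE1 == "L"]
  expect_equal(sum(f[leu]), 1)
  expect_error(synonymousFrequencies(stats::setNames(numeric(64), ALL64),
                                     CODE1), "all-zero")
})

test_that("the engineered Ser family reproduces the reference worked example", {
  ref <- synonymousFrequencies(humanLikeTable(), CODE1)
  expect_equal(synFreq(ref)[["TCG"]], 0.0567)
})

test_that("GC metrics count overall and third-position G+C", {
  expect_equal(unname(gcMetrics("GCGCGC")), c(100, 100))
  expect_equal(unname(gcMetrics("ATATAT")), c(0, 0))
  expect_equal(unname(gcMetrics("ATGTCG")), c(50, 100))
})

test_that("RCDI is 1 for matched usage and 1/CiFh for a single rare codon", {
  ref <- synonymousFrequencies(humanLikeTable(), CODE1)
  r <- rcdi(strrep("TCG", 100), ref)
  expect_equal(rcdiValue(r), 1 / 0.0567, tolerance = 1e-12)

  ## gene realizing the uniform reference's frequencies exactly
  refU <- synonymousFrequencies(uniformTable(), CODE1)
  leu <- paste(ALL64[CODE1 == "L"], collapse = "")
  expect_equal(rcdiValue(rcdi(leu, refU)), 1, tolerance = 1e-12)
})

test_that("a 4-codon toy gene matches a hand-computed sum", {
  ## reference: Leu TTA 1/4, TTG 3/4 (other Leu codons absent);
  ## Lys AAA 2/3, AAG 1/3
  vals <- stats::setNames(rep(1, 64), ALL64)
  vals[ALL64[CODE1 == "L"]] <- 0
  vals[c("TTA", "TTG")] <- c(1, 3)
  vals[c("AAA", "AAG")] <- c(2, 1)
  ref <- synonymousFrequencies(codonUsageTable(vals, scale = "counts"), CODE1)
  ## gene: TTA TTA AAG AAG -> CiFa(TTA)=1, CiFa(AAG)=1
  ## by hand: ((1/0.25)*2 + (1/(1/3))*2)/4 = (8 + 6)/4 = 3.5
  r <- rcdi("TTATTAAAGAAG", ref)
  expect_equal(rcdiValue(r), 3.5, tolerance = 1e-12)
  expect_equal(contributions(r)[["TTA"]], 8)
  expect_equal(contributions(r)[["AAG"]], 6)
})

test_that("reference-absent codons error unless a pseudo-frequency is given", {
  vals <- stats::setNames(rep(1, 64), ALL64)
  vals["TTA"] <- 0
  ref <- synonymousFrequencies(codonUsageTable(vals, scale = "counts"), CODE1)
  expect_error(rcdi("TTATTATTA", ref), "absent from reference.*TTA")
  r <- rcdi("TTATTATTA", ref, pseudoFreq = TRUE)
  expect_true(is.finite(rcdiValue(r)))
  expect_gt(rcdiValue(r), 1)
  ## numeric pseudo-frequency also accepted
  expect_true(is.finite(rcdiValue(rcdi("TTATTATTA", ref, pseudoFreq = 0.01))))
})

test_that("internal stop codons warn but do not abort", {
  refU <- synonymousFrequencies(uniformTable(), CODE1)
  r <- rcdi("ATGTAAATGTAA", refU)
  expect_match(r@warnings, "internal stop", all = FALSE)
  expect_equal(nCodons(r), 2L)
})

test_that("RCDI respects its bounds and bookkeeping over random inputs", {
  set.seed(42)
  refTab <- randomUsageTable()
  ref <- synonymousFrequencies(refTab, CODE1)
  fmin <- min(synFreq(ref)[CODE1 != "*"])
  for (i in 1:200) {
    g <- randomGene(sample(5:60, 1))
    r <- rcdi(g, ref)
    expect_gte(rcdiValue(r), 1 - 1e-9)
    present <- names(contributions(r))[contributions(r) > 0]
    bound <- 1 / min(synFreq(ref)[present])
    expect_lte(rcdiValue(r), bound + 1e-9)
    ## contribution bookkeeping identity
    expect_equal(sum(contributions(r)) / nCodons(r), rcdiValue(r),
                 tolerance = 1e-9)
  }
})

test_that("RCDI is invariant under codon-order permutation", {
  set.seed(7)
  ref <- synonymousFrequencies(randomUsageTable(), CODE1)
  g <- randomGene(40)
  codons <- substring(g, seq(1, nchar(g) - 2, 3), seq(3, nchar(g), 3))
  for (i in 1:10) {
    shuffled <- paste(sample(codons), collapse = "")
    expect_equal(rcdiValue(rcdi(shuffled, ref)), rcdiValue(rcdi(g, ref)),
                 tolerance = 1e-12)
  }
})

test_that("rcdi agrees with the naive per-codon oracle to 1e-12", {
  set.seed(99)
  for (i in 1:50) {
    ref <- synonymousFrequencies(randomUsageTable(), CODE1)
    g <- randomGene(sample(4:30, 1))
    expect_equal(rcdiValue(rcdi(g, ref)),
                 naiveRcdi(g, synFreq(ref), CODE1),
                 tolerance = 1e-12)
  }
})

test_that("computeRcdi scores each gene on its own usage and tabulates", {
  set.seed(5)
  ref <- synonymousFrequencies(uniformTable(), CODE1)
  seqs <- c(g1 = randomGene(30), g2 = randomGene(45))
  res <- computeRcdi(seqs, ref)
  expect_named(res, c("g1", "g2"))
  expect_equal(rcdiValue(res$g1), rcdiValue(rcdi(seqs[["g1"]], ref)))
  tab <- rcdiTable(res)
  expect_equal(tab$gene_id, c("g1", "g2"))
  expect_equal(ncol(tab), 5L + 64L)
  expect_equal(tab$rcdi, vapply(res, rcdiValue, numeric(1L)),
               ignore_attr = TRUE)
})
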