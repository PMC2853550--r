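test_that("composition profiles pool composition, GC and length", {
  p <- compositionProfile(c(g = strrep("ATG", 10)), CODE1)
  expect_equal(aaFreq(p)[["M"]], 1)
  expect_equal(meanLengthCodons(p), 10L)

  p2 <- compositionProfile(c(a = strrep("ATG", 9), b = strrep("ATG", 15)),
                           CODE1)
  expect_equal(meanLengthCodons(p2), 12L)

  ## pooled GC of an all-GC and an all-AT gene of equal length
  p3 <- compositionProfile(c(a = strrep("GGG", 10), b = strrep("AAA", 10)),
                           CODE1)
  expect_equal(gcTarget(p3), 0.5)

  expect_error(compositionProfile(character(0), CODE1), "no sequences")
})

test_that("amino-acid pooling is weighted by gene length", {
  ## 30 Met codons + 10 Lys codons -> M 0.75, K 0.25 regardless of gene split
  p <- compositionProfile(c(a = strrep("ATG", 30), b = strrep("AAA", 10)),
                          CODE1)
  expect_equal(aaFreq(p)[["M"]], 0.75)
  expect_equal(aaFreq(p)[["K"]], 0.25)
})

test_that("the GC weight solver hits its closed-form solution", {
  ## single two-fold family (Phe: TTT gc=0, TTC gc=1):
  ## E[GC](w) = (1/3) * w/(1+w); target 0.2 -> w = 1.5 exactly
  prof <- methods::new("CompositionProfile",
                       aaFreq = c(F = 1), gcTarget = 0.2,
                       meanLengthCodons = 10L,
                       aaTransitions = matrix(1, 1, 1,
                                              dimnames = list("F", "F")))
  expect_equal(gcWeightSolve(prof, CODE1), 1.5, tolerance = 1e-7)

  ## identity case: target equal to the unweighted expectation -> w = 1
  prof2 <- methods::new("CompositionProfile",
                        aaFreq = c(F = 1), gcTarget = 1 / 6,
                        meanLengthCodons = 10L,
                        aaTransitions = matrix(1, 1, 1,
                                               dimnames = list("F", "F")))
  expect_equal(gcWeightSolve(prof2, CODE1), 1, tolerance = 1e-7)

  ## monotonicity: larger target, larger weight
  targets <- c(0.05, 0.15, 0.25, 0.32)
  ws <- vapply(targets, function(t) {
    pr <- methods::new("CompositionProfile", aaFreq = c(F = 1), gcTarget = t,
                       meanLengthCodons = 10L,
                       aaTransitions = matrix(1, 1, 1,
                                              dimnames = list("F", "F")))
    gcWeightSolve(pr, CODE1)
  }, numeric(1L))
  expect_true(all(diff(ws) > 0))

  ## outside the achievable interval is an error naming the interval
  prof3 <- methods::new("CompositionProfile",
                        aaFreq = c(F = 1), gcTarget = 0.8,
                        meanLengthCodons = 10L,
                        aaTransitions = matrix(1, 1, 1,
                                               dimnames = list("F", "F")))
  expect_error(gcWeightSolve(prof3, CODE1), "achievable")
})

test_that("random CDS match length and composition constraints", {
  set.seed(21)
  ## no degeneracy: all-Met profile forces ATG repeats
  pM <- compositionProfile(c(g = strrep("ATG", 12)), CODE1)
  s <- generateRandomCds(pM, CODE1, n = 2)
  expect_equal(as.character(s), c(random_1 = strrep("ATG", 12),
                                  random_2 = strrep("ATG", 12)))

  ## Phe-only profile at the maximum achievable GC -> all TTC
  pF <- methods::new("CompositionProfile",
                     aaFreq = c(F = 1), gcTarget = 1 / 3,
                     meanLengthCodons = 9L,
                     aaTransitions = matrix(1, 1, 1,
                                            dimnames = list("F", "F")))
  s2 <- generateRandomCds(pF, CODE1, n = 1)
  expect_equal(as.character(s2[[1L]]), strrep("TTC", 9))

  ## generated sequences never contain stop codons
  set.seed(8)
  p <- compositionProfile(queryGenes(3, 100), CODE1)
  rnd <- generateRandomCds(p, CODE1, n = 20, lengthCodons = 200)
  for (i in seq_len(20)) {
    cc <- countCodons(as.character(rnd[[i]]), CODE1, includeStops = TRUE)
    expect_equal(sum(cc$counts[ALL64[CODE1 == "*"]]), 0L)
    expect_equal(cc$total, 200L)
  }
})

test_that("markov generation reproduces the stationary composition", {
  set.seed(31)
  queries <- queryGenes(3, 150)
  p <- compositionProfile(queries, CODE1)
  rnd <- generateRandomCds(p, CODE1, n = 5, method = "markov",
                           lengthCodons = 4000)
  pooled <- compositionProfile(as.character(rnd), CODE1)
  tv <- sum(abs(aaFreq(pooled)[names(aaFreq(p))] - aaFreq(p))) / 2
  expect_lt(tv, 0.05)
})

test_that("tolerance factors are zero at the median and calibrated at n=50", {
  expect_equal(as.numeric(toleranceFactor(10, 0.5, 0.5)), 0, tolerance = 1e-9)
  expect_equal(as.numeric(toleranceFactor(1000, 0.5, 0.5)), 0,
               tolerance = 1e-9)
  expect_error(toleranceFactor(1, 0.95, 0.99), ">= 2")
  expect_error(toleranceFactor(50, 1.2, 0.99), "strictly in")

  ## Monte-Carlo oracle: with k(50, 0.95, 0.99), mean + k*sd of a standard
  ## normal sample of 50 should exceed z_0.99 in ~95% of samples
  set.seed(61)
  k <- as.numeric(toleranceFactor(50, 0.95, 0.99))
  hits <- replicate(2000, {
    x <- rnorm(50)
    mean(x) + k * sd(x) > qnorm(0.99)
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.02)
})

test_that("tolerance factors increase with confidence and coverage", {
  k0 <- as.numeric(toleranceFactor(100, 0.95, 0.99))
  expect_gt(as.numeric(toleranceFactor(100, 0.99, 0.99)), k0)
  expect_gt(as.numeric(toleranceFactor(100, 0.95, 0.999)), k0)
})

test_that("expectedRcdi is reproducible and equals its defining identity", {
  set.seed(77)
  queries <- queryGenes(2, 80)
  ref <- synonymousFrequencies(uniformTable(), CODE1)
  e1 <- expectedRcdi(queries, ref, nRandom = 40, seed = 123)
  e2 <- expectedRcdi(queries, ref, nRandom = 40, seed = 123)
  expect_identical(randomRcdi(e1), randomRcdi(e2))
  expect_identical(ercdiValue(e1), ercdiValue(e2))
  ## identity: ercdi = mean + k * sd with the reported k
  expect_equal(ercdiValue(e1),
               mean(randomRcdi(e1)) + e1@k * sd(randomRcdi(e1)),
               tolerance = 1e-12)
  expect_gte(ercdiValue(e1), mean(randomRcdi(e1)))
  ## different seeds give different nulls
  e3 <- expectedRcdi(queries, ref, nRandom = 40, seed = 124)
  expect_false(identical(randomRcdi(e1), randomRcdi(e3)))
})

test_that("the eRCDI limit rises with coverage and confidence", {
  set.seed(55)
  queries <- queryGenes(2, 80)
  ref <- synonymousFrequencies(uniformTable(), CODE1)
  base <- expectedRcdi(queries, ref, nRandom = 60, seed = 9,
                       confidence = 0.9, coverage = 0.95)
  upCov <- expectedRcdi(queries, ref, nRandom = 60, seed = 9,
                        confidence = 0.9, coverage = 0.99)
  upConf <- expectedRcdi(queries, ref, nRandom = 60, seed = 9,
                         confidence = 0.99, coverage = 0.95)
  expect_identical(randomRcdi(base), randomRcdi(upCov))
  expect_gt(ercdiValue(upCov), ercdiValue(base))
  expect_gt(ercdiValue(upConf), ercdiValue(base))
})

test_that("seeded eRCDI runs serialize to byte-identical JSON reports", {
  set.seed(13)
  queries <- queryGenes(2, 60)
  ref <- synonymousFrequencies(uniformTable(), CODE1)
  run <- function() {
    res <- computeRcdi(queries, ref)
    e <- expectedRcdi(queries, ref, nRandom = 30, seed = 555)
    writeReport(res, e, format = "json")
  }
  expect_identical(run(), run())
})
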