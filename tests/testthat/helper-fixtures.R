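## Fixture builders shared by the tests. Everything is generated in code;
## seeds are fixed by the calling tests.

CODE1 <- geneticCode(1)
ALL64 <- names(CODE1)
SENSE <- ALL64[CODE1 != "*"]

## Uniform reference: every codon weighted 1 (every family uniform).
uniformTable <- function() {
  codonUsageTable(stats::setNames(rep(1, 64), ALL64), scale = "counts")
}

## Human-like reference in which the Ser family gives TCG a within-family
## relative frequency of exactly 0.0567 (567 of 10000 Ser codons); other
## families uniform.
humanLikeTable <- function() {
  vals <- stats::setNames(rep(100, 64), ALL64)
  ser <- ALL64[CODE1 == "S"]
  vals["TCG"] <- 567
  vals[setdiff(ser, "TCG")] <- (10000 - 567) / 5
  codonUsageTable(vals, scale = "counts")
}

## Random strictly positive usage table (no zero-frequency codons).
randomUsageTable <- function() {
  codonUsageTable(stats::setNames(stats::runif(64, 0.5, 100), ALL64),
                  scale = "counts")
}

## Random CDS of n codons drawn uniformly from the sense codons.
randomGene <- function(n) {
  paste(sample(SENSE, n, replace = TRUE), collapse = "")
}

## Random integer family counts and the gene + reference table realizing
## them exactly: the gene's CiFa equals the reference's CiFh by construction.
matchedPair <- function(nFamilies = 6L, maxCount = 5L) {
  fams <- split(SENSE, CODE1[SENSE])
  fams <- fams[lengths(fams) > 1L]
  pick <- sample(names(fams), nFamilies)
  counts <- stats::setNames(integer(64L), ALL64)
  for (aa in pick) {
    cods <- fams[[aa]]
    ## every codon of a picked family gets >= 1, so its CiFh is never 0
    counts[cods] <- sample(seq_len(maxCount), length(cods), replace = TRUE)
  }
  refVals <- counts
  refVals[refVals == 0 & CODE1 != "*"] <- 1   # keep unused families defined
  gene <- paste(sample(rep(ALL64, counts)), collapse = "")
  list(gene = gene,
       reference = synonymousFrequencies(
         codonUsageTable(refVals + 0.0, scale = "counts"), CODE1),
       counts = counts)
}

## Independent RCDI oracle: a literal per-codon loop over the defining sum,
## sharing no code with rcdi().
naiveRcdi <- function(gene, refFreq, code) {
  n <- nchar(gene)
  codons <- substring(gene, seq(1, n - 2, 3), seq(3, n, 3))
  codons <- codons[code[codons] != "*" & !grepl("[^ACGT]", codons)]
  counts <- table(codons)
  total <- 0
  for (c1 in codons) {
    fam <- names(code)[code == code[[c1]]]
    famTotal <- sum(counts[intersect(fam, names(counts))])
    cifa <- counts[[c1]] / famTotal
    total <- total + cifa / refFreq[[c1]]
  }
  total / length(codons)
}

## Query set used by the eRCDI tests: moderately GC-biased genes sampled
## from a fixed codon pool (seeded by the caller).
queryGenes <- function(n = 3L, len = 120L) {
  pool <- c("ATG", "GCC", "GCA", "TTA", "CTG", "TCC", "AAA", "GAG",
            "GGC", "TAT", "CAC", "GTG")
  stats::setNames(
    vapply(seq_len(n),
           function(i) paste(sample(pool, len, replace = TRUE), collapse = ""),
           character(1L)),
    paste0("q", seq_len(n)))
}
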