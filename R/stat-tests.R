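#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of a numeric vector against a normal distribution
#' with the sample's own mean and SD. Because the parameters are estimated
#' from the same data, the reported p-value uses the Lilliefors correction
#' (\code{nortest::lillie.test}); the uncorrected one-sample KS p-value is
#' also returned for comparison with implementations that skip the
#' correction.
#'
#' @param values Numeric vector, at least 8 values with positive SD.
#' @return List: \code{statistic} (the KS D), \code{pvalue} (Lilliefors),
#'   \code{plainPvalue} (uncorrected), \code{method}.
#'
#' @examples
#' set.seed(1)
#' ksNormality(rnorm(100))$pvalue
#'
#' @importFrom nortest lillie.test
#' @importFrom stats ks.test
#' @export
ksNormality <- function(values) {
  if (!is.numeric(values) || length(values) < 8L)
    stop("at least 8 values are required; increase nRandom", call. = FALSE)
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0)
    stop("degenerate sample: standard deviation is zero", call. = FALSE)
  lil <- nortest::lillie.test(values)
  plain <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s))
  list(statistic = unname(lil$statistic),
       pvalue = lil$p.value,
       plainPvalue = plain$p.value,
       method = "lilliefors")
}

## Chi-square goodness-of-fit of observed counts against expected counts,
## pooling categories with expected < 1 into one (so no expected cell is
## tiny). Returns statistic, df and upper-tail p.
.chisqGof <- function(observed, expected) {
  keep <- expected > 0
  observed <- observed[keep]; expected <- expected[keep]
  small <- expected < 1
  if (any(small) && sum(small) < length(expected)) {
    observed <- c(observed[!small], sum(observed[small]))
    expected <- c(expected[!small], sum(expected[small]))
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- length(expected) - 1L
  p <- if (df >= 1L) stats::pchisq(stat, df, lower.tail = FALSE)
       else if (stat < 1e-12) 1 else NA_real_
  list(statistic = stat, df = df, pvalue = p)
}

#' Chi-square homogeneity of a query set
#'
#' Tests whether the query sequences are homogeneous in amino-acid
#' composition and in G+C content: each sequence is compared against the
#' pooled composition of the whole set with a chi-square goodness-of-fit
#' test. For the amino-acid test, categories with expected count below 1
#' are pooled into one and df is the remaining category count minus 1; the
#' G+C test compares the G+C vs A+T nucleotide counts (df = 1). Counted
#' codons only (no stops, no ambiguity codons).
#'
#' @param seqs At least two coding sequences.
#' @param code Genetic code map.
#' @return \code{data.frame} with one row per sequence: \code{gene_id},
#'   \code{aa_statistic}, \code{aa_df}, \code{aa_pvalue},
#'   \code{gc_statistic}, \code{gc_pvalue}.
#'
#' @importFrom stats pchisq
#' @export
chi2Homogeneity <- function(seqs, code) {
  code <- .checkCode(code)
  v <- .asCdsVector(seqs)
  if (length(v) < 2L)
    stop("homogeneity testing needs at least 2 sequences", call. = FALSE)
  aas <- sort(unique(code[code != "*"]))
  perGene <- lapply(v, function(s) {
    cc <- countCodons(s, code, includeStops = FALSE)
    aaCounts <- tapply(cc$counts, code[names(cc$counts)], sum)
    aaCounts <- aaCounts[aas]
    aaCounts[is.na(aaCounts)] <- 0
    names(aaCounts) <- aas
    gcCount <- sum(CODON_GC[cc$codons])
    list(aa = aaCounts, gc = gcCount, nt = 3L * length(cc$codons))
  })
  pooledAa <- Reduce(`+`, lapply(perGene, `[[`, "aa"))
  aaFreq <- pooledAa / sum(pooledAa)
  gcFrac <- sum(vapply(perGene, function(x) as.numeric(x$gc), numeric(1L))) /
    sum(vapply(perGene, function(x) as.numeric(x$nt), numeric(1L)))

  rows <- lapply(names(v), function(id) {
    g <- perGene[[id]]
    aaRes <- .chisqGof(as.numeric(g$aa), sum(g$aa) * as.numeric(aaFreq))
    obs <- c(g$gc, g$nt - g$gc)
    exp <- g$nt * c(gcFrac, 1 - gcFrac)
    if (any(exp == 0)) {
      gcStat <- if (all(obs[exp == 0] == 0)) 0 else Inf
      gcP <- if (is.finite(gcStat)) 1 else 0
    } else {
      gcStat <- sum((obs - exp)^2 / exp)
      gcP <- stats::pchisq(gcStat, 1L, lower.tail = FALSE)
    }
    data.frame(gene_id = id,
               aa_statistic = aaRes$statistic, aa_df = aaRes$df,
               aa_pvalue = aaRes$pvalue,
               gc_statistic = gcStat, gc_pvalue = gcP,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
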