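#' CodonUsageTable: reference codon usage for a genome
#'
#' Holds one non-negative value per codon (all 64), either raw counts or
#' frequencies per thousand codons, as distributed by codon-usage databases.
#'
#' @slot values Named numeric vector of length 64 (names are DNA codons).
#' @slot scale Either \code{"counts"} or \code{"per_thousand"}.
#'
#' @seealso \code{\link{codonUsageTable}}, \code{\link{readCodonUsageTable}}
#' @exportClass CodonUsageTable
setClass("CodonUsageTable",
         representation(values = "numeric", scale = "character"))

setValidity("CodonUsageTable", function(object) {
  v <- object@values
  if (length(v) != 64L || is.null(names(v)) || !setequal(names(v), CODONS))
    return("'values' must be a named numeric of length 64 covering all codons")
  if (anyNA(v) || any(v < 0))
    return("codon usage values must be non-negative and non-missing")
  if (!(object@scale %in% c("counts", "per_thousand")))
    return("scale must be 'counts' or 'per_thousand'")
  if (object@scale == "per_thousand" && abs(sum(v) - 1000) > 0.5)
    return(sprintf("per-thousand values must sum to 1000 (+/- 0.5); got %.3f",
                   sum(v)))
  TRUE
})

#' SynonymousFrequencyTable: within-family relative codon frequencies
#'
#' For every codon, its frequency relative to the other codons encoding the
#' same amino acid (its synonymous family) under a given genetic code. This
#' is the quantity the RCDI compares between a test gene (CiFa) and a
#' reference genome (CiFh). Families with no observations carry \code{NaN}
#' (undefined, distinct from zero). Stop codons form their own family.
#'
#' @slot freq Named numeric of length 64; within-family relative frequencies.
#' @slot values The raw values the table was built from (counts or
#'   per-thousand), kept for pseudo-frequency handling and CAI weights.
#' @slot code The 64-codon genetic code map used to define families.
#' @slot codeId NCBI translation table identifier (as character), or "" when
#'   the code was supplied directly.
#'
#' @seealso \code{\link{synonymousFrequencies}}
#' @exportClass SynonymousFrequencyTable
setClass("SynonymousFrequencyTable",
         representation(freq = "numeric", values = "numeric",
                        code = "character", codeId = "character"))

setValidity("SynonymousFrequencyTable", function(object) {
  f <- object@freq
  if (length(f) != 64L || is.null(names(f)) || !setequal(names(f), CODONS))
    return("'freq' must be a named numeric of length 64")
  fam <- split(f, object@code[names(f)])
  for (aa in names(fam)) {
    ff <- fam[[aa]]
    if (all(is.nan(ff))) next
    if (any(is.nan(ff)))
      return(sprintf("family '%s' mixes defined and undefined frequencies", aa))
    if (abs(sum(ff) - 1) > 1e-9)
      return(sprintf("family '%s' frequencies sum to %.12f, not 1", aa, sum(ff)))
  }
  TRUE
})

#' RcdiResult: per-gene outcome of an RCDI computation
#'
#' @slot geneId Sequence identifier.
#' @slot rcdi The Relative Codon Deoptimization Index (>= 1).
#' @slot contributions Named numeric of length 64: the per-codon terms
#'   (CiFa/CiFh)*Ni whose sum divided by \code{nCodons} is the RCDI.
#' @slot gcPercent,gc3Percent G+C percentages over the counted codons
#'   (overall and third position).
#' @slot nCodons Number of codons entering the index (N).
#' @slot excludedCodons Number of codons dropped for ambiguity characters.
#' @slot warnings Character vector of per-gene notes (e.g. internal stops).
#'
#' @seealso \code{\link{rcdi}}
#' @exportClass RcdiResult
setClass("RcdiResult",
         representation(geneId = "character", rcdi = "numeric",
                        contributions = "numeric", gcPercent = "numeric",
                        gc3Percent = "numeric", nCodons = "integer",
                        excludedCodons = "integer", warnings = "character"))

setValidity("RcdiResult", function(object) {
  if (object@nCodons < 1L) return("nCodons must be >= 1")
  if (object@rcdi < 1 - 1e-9) return("rcdi below its lower bound of 1")
  s <- sum(object@contributions, na.rm = TRUE) / object@nCodons
  if (abs(s - object@rcdi) > 1e-9)
    return("contributions do not reproduce the RCDI")
  TRUE
})

#' CompositionProfile: composition targets for the random-sequence null
#'
#' Summarizes a query set by its pooled amino-acid composition, pooled G+C
#' fraction and mean length; random sequences for the expected-RCDI null are
#' generated to match it.
#'
#' @slot aaFreq Named numeric: amino-acid frequencies (sum 1, stops excluded).
#' @slot gcTarget Pooled G+C fraction of the counted codons, in [0, 1].
#' @slot meanLengthCodons Rounded mean query length in codons.
#' @slot aaTransitions Row-stochastic first-order amino-acid transition
#'   matrix estimated from the queries (used by the Markov generator).
#'
#' @seealso \code{\link{compositionProfile}}, \code{\link{generateRandomCds}}
#' @exportClass CompositionProfile
setClass("CompositionProfile",
         representation(aaFreq = "numeric", gcTarget = "numeric",
                        meanLengthCodons = "integer",
                        aaTransitions = "matrix"))

setValidity("CompositionProfile", function(object) {
  if (abs(sum(object@aaFreq) - 1) > 1e-9)
    return("amino-acid frequencies must sum to 1")
  if (any(object@aaFreq < 0)) return("negative amino-acid frequency")
  if (object@gcTarget < 0 || object@gcTarget > 1)
    return("gcTarget must lie in [0, 1]")
  if (object@meanLengthCodons < 1L) return("mean length must be >= 1 codon")
  TRUE
})

#' ErcdiResult: the expected-RCDI null and its statistics
#'
#' @slot randomRcdi RCDI values of the generated random sequences.
#' @slot randomMean,randomSd Mean and sample SD (n-1) of \code{randomRcdi}.
#' @slot k One-sided normal tolerance factor used for the limit.
#' @slot ercdi The expected RCDI: \code{randomMean + k * randomSd}.
#' @slot ksStatistic,ksPvalue,ksPlainPvalue Kolmogorov-Smirnov normality
#'   check of the random RCDIs: statistic, Lilliefors-corrected p, and the
#'   uncorrected one-sample KS p.
#' @slot chi2 Per-query chi-square homogeneity results (data.frame), or a
#'   zero-row frame when fewer than two queries were supplied.
#' @slot profile The \code{CompositionProfile} the null was matched to.
#' @slot nRandom Number of random sequences.
#' @slot config List recording method, confidence, coverage, seed, length
#'   rule and the tolerance-factor algorithm used.
#'
#' @seealso \code{\link{expectedRcdi}}
#' @exportClass ErcdiResult
setClass("ErcdiResult",
         representation(randomRcdi = "numeric", randomMean = "numeric",
                        randomSd = "numeric", k = "numeric", ercdi = "numeric",
                        ksStatistic = "numeric", ksPvalue = "numeric",
                        ksPlainPvalue = "numeric", chi2 = "data.frame",
                        profile = "CompositionProfile", nRandom = "integer",
                        config = "list"))

setValidity("ErcdiResult", function(object) {
  if (object@nRandom < 2L) return("nRandom must be >= 2")
  if (length(object@randomRcdi) != object@nRandom)
    return("randomRcdi length disagrees with nRandom")
  if (object@ercdi < object@randomMean - 1e-12)
    return("ercdi must not fall below the random mean")
  TRUE
})

#' RelativeAdaptivenessTable: CAI weights
#'
#' Per-codon relative adaptiveness: the codon's reference frequency divided
#' by the highest frequency in its synonymous family; the preferred codon of
#' every family has weight 1.
#'
#' @slot w Named numeric of length 64 in [0, 1] (stop codons carry NA;
#'   zero weights occur only when pseudo-counting is disabled).
#' @slot code The genetic code map defining the families.
#'
#' @seealso \code{\link{caiWeights}}, \code{\link{cai}}
#' @exportClass RelativeAdaptivenessTable
setClass("RelativeAdaptivenessTable",
         representation(w = "numeric", code = "character"))

setValidity("RelativeAdaptivenessTable", function(object) {
  w <- object@w
  if (length(w) != 64L || is.null(names(w)) || !setequal(names(w), CODONS))
    return("'w' must be a named numeric of length 64")
  ok <- !is.na(w)
  ## zero weights are legal only when pseudo-counting was disabled; cai()
  ## refuses to use them
  if (any(w[ok] < 0) || any(w[ok] > 1 + 1e-12))
    return("defined weights must lie in [0, 1]")
  TRUE
})
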