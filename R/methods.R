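## Accessors and show methods for the S4 result classes.

#' @describeIn codonUsageTable Codon values of a table, in canonical order.
#' @export
cuValues <- function(x) {
  stopifnot(is(x, "CodonUsageTable"))
  x@values[CODONS]
}

#' @describeIn codonUsageTable Scale of a table ("counts" or "per_thousand").
#' @export
cuScale <- function(x) {
  stopifnot(is(x, "CodonUsageTable"))
  x@scale
}

#' @describeIn synonymousFrequencies Within-family relative frequencies
#'   (named numeric of length 64; NaN marks families with no observations).
#' @export
synFreq <- function(x) {
  stopifnot(is(x, "SynonymousFrequencyTable"))
  x@freq[CODONS]
}

#' @describeIn synonymousFrequencies Genetic code map backing the table.
#' @export
synCode <- function(x) {
  stopifnot(is(x, "SynonymousFrequencyTable"))
  x@code
}

#' @describeIn rcdi Gene identifier of a result.
#' @export
geneId <- function(x) {
  stopifnot(is(x, "RcdiResult"))
  x@geneId
}

#' @describeIn rcdi Numeric RCDI value of a result.
#' @export
rcdiValue <- function(x) {
  stopifnot(is(x, "RcdiResult"))
  x@rcdi
}

#' @describeIn rcdi Per-codon contribution terms (CiFa/CiFh)*Ni.
#' @export
contributions <- function(x) {
  stopifnot(is(x, "RcdiResult"))
  x@contributions[CODONS]
}

#' @describeIn rcdi G+C percentage over counted codons.
#' @export
gcPercent <- function(x) {
  stopifnot(is(x, "RcdiResult"))
  x@gcPercent
}

#' @describeIn rcdi Third-position G+C percentage over counted codons.
#' @export
gc3Percent <- function(x) {
  stopifnot(is(x, "RcdiResult"))
  x@gc3Percent
}

#' @describeIn rcdi Number of codons that entered the index (N).
#' @export
nCodons <- function(x) {
  stopifnot(is(x, "RcdiResult"))
  x@nCodons
}

#' @describeIn expectedRcdi Expected RCDI (the upper tolerance limit).
#' @export
ercdiValue <- function(x) {
  stopifnot(is(x, "ErcdiResult"))
  x@ercdi
}

#' @describeIn expectedRcdi RCDI values of the generated random sequences.
#' @export
randomRcdi <- function(x) {
  stopifnot(is(x, "ErcdiResult"))
  x@randomRcdi
}

#' @describeIn expectedRcdi KS normality check as a named list (statistic,
#'   Lilliefors p-value, plain KS p-value).
#' @export
ksTest <- function(x) {
  stopifnot(is(x, "ErcdiResult"))
  list(statistic = x@ksStatistic, pvalue = x@ksPvalue,
       plainPvalue = x@ksPlainPvalue)
}

#' @describeIn expectedRcdi Per-query chi-square homogeneity results.
#' @export
chi2Tests <- function(x) {
  stopifnot(is(x, "ErcdiResult"))
  x@chi2
}

#' @describeIn expectedRcdi Composition profile the null was matched to.
#' @export
nullProfile <- function(x) {
  stopifnot(is(x, "ErcdiResult"))
  x@profile
}

#' @describeIn compositionProfile Amino-acid frequencies of a profile.
#' @export
aaFreq <- function(x) {
  stopifnot(is(x, "CompositionProfile"))
  x@aaFreq
}

#' @describeIn compositionProfile Target G+C fraction of a profile.
#' @export
gcTarget <- function(x) {
  stopifnot(is(x, "CompositionProfile"))
  x@gcTarget
}

#' @describeIn compositionProfile Rounded mean query length in codons.
#' @export
meanLengthCodons <- function(x) {
  stopifnot(is(x, "CompositionProfile"))
  x@meanLengthCodons
}

#' @describeIn caiWeights Weight vector of a RelativeAdaptivenessTable.
#' @export
caiW <- function(x) {
  stopifnot(is(x, "RelativeAdaptivenessTable"))
  x@w[CODONS]
}

#' @export
setMethod("show", "CodonUsageTable", function(object) {
  cat("CodonUsageTable (scale:", object@scale, ")\n")
  cat("  sum of values:", format(sum(object@values)), "\n")
  cat("  top codons:", paste(names(sort(object@values, decreasing = TRUE))[1:5],
                             collapse = " "), "\n")
})

#' @export
setMethod("show", "SynonymousFrequencyTable", function(object) {
  nUndef <- sum(is.nan(object@freq))
  cat("SynonymousFrequencyTable (genetic code",
      if (nzchar(object@codeId)) object@codeId else "custom", ")\n")
  cat("  undefined codons:", nUndef, "\n")
  defined <- object@freq[!is.nan(object@freq) & object@code != "*"]
  cat("  min defined CiF:", format(min(defined)), "\n")
})

#' @export
setMethod("show", "RcdiResult", function(object) {
  cat("RcdiResult for", object@geneId, "\n")
  cat(sprintf("  RCDI = %.4f over %d codons (%d excluded)\n",
              object@rcdi, object@nCodons, object@excludedCodons))
  cat(sprintf("  %%G+C = %.2f, %%G+C3 = %.2f\n",
              object@gcPercent, object@gc3Percent))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

#' @export
setMethod("show", "CompositionProfile", function(object) {
  cat("CompositionProfile:", length(object@aaFreq), "amino acids,",
      "GC target", format(object@gcTarget, digits = 4), ",",
      "mean length", object@meanLengthCodons, "codons\n")
})

#' @export
setMethod("show", "ErcdiResult", function(object) {
  cat("ErcdiResult from", object@nRandom, "random sequences (",
      object@config$method %||% "poisson", ")\n")
  cat(sprintf("  random RCDI: mean %.4f, sd %.4f\n",
              object@randomMean, object@randomSd))
  cat(sprintf("  eRCDI = %.4f (k = %.4f, confidence %.2f, coverage %.2f)\n",
              object@ercdi, object@k,
              object@config$confidence %||% NA_real_,
              object@config$coverage %||% NA_real_))
  cat(sprintf("  KS normality: D = %.4f, Lilliefors p = %.4g\n",
              object@ksStatistic, object@ksPvalue))
})
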