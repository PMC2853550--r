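#' Count the codons of a coding sequence
#'
#' Splits a CDS into consecutive codons from the first nucleotide and counts
#' each of the 64 codons. Codons containing ambiguity characters are
#' excluded and tallied; stop codons are excluded from the count unless
#' \code{includeStops = TRUE}.
#'
#' @param seq A CDS: character string, \code{DNAString}, or length-1
#'   \code{DNAStringSet}. Length must be a positive multiple of 3.
#' @param code Genetic code map from \code{\link{geneticCode}}.
#' @param includeStops Count stop codons too.
#' @return List with \code{counts} (named integer, length 64), \code{total}
#'   (N, the number of counted codons), \code{excluded} (ambiguous codons
#'   dropped), \code{stops} (stop codons seen) and \code{internalStops}
#'   (stop codons before the final codon).
#'
#' @examples
#' cc <- countCodons("ATGTCGTCG", geneticCode(1))
#' cc$counts[c("ATG", "TCG")]
#'
#' @export
countCodons <- function(seq, code, includeStops = FALSE) {
  code <- .checkCode(code)
  s <- .asCdsString(seq)
  codons <- .splitCodons(s)
  ambiguous <- grepl("[^ACGT]", codons)
  clean <- codons[!ambiguous]
  isStop <- code[clean] == "*"
  ## internal stops: stop codons that are not the final codon of the gene
  stopIdx <- which(!ambiguous)[isStop]
  internalStops <- sum(stopIdx < length(codons))
  counted <- if (includeStops) clean else clean[!isStop]
  counts <- table(factor(counted, levels = CODONS))
  counts <- stats::setNames(as.integer(counts), CODONS)
  list(counts = counts,
       total = sum(counts),
       excluded = sum(ambiguous),
       stops = sum(isStop),
       internalStops = internalStops,
       codons = counted)
}

#' Within-family synonymous codon frequencies
#'
#' Normalizes per-codon values (counts from a gene, or a reference
#' \code{\linkS4class{CodonUsageTable}}) within each synonymous family of a
#' genetic code: \code{freq[c] = value[c] / sum(values of codons encoding
#' the same amino acid)}. Built from a test gene this is CiFa; built from
#' the reference genome it is CiFh — the two sides of the RCDI. Families
#' with no observations are marked \code{NaN} (undefined, not zero);
#' single-codon families have frequency exactly 1.
#'
#' @param x A \code{CodonUsageTable}, the list returned by
#'   \code{\link{countCodons}}, or a named numeric vector of per-codon
#'   values.
#' @param code Genetic code map from \code{\link{geneticCode}}.
#' @return A \code{\linkS4class{SynonymousFrequencyTable}}.
#'
#' @examples
#' code <- geneticCode(1)
#' vals <- stats::setNames(rep(1, 64), names(code))
#' ft <- synonymousFrequencies(codonUsageTable(vals), code)
#' synFreq(ft)[["ATG"]]   # single-codon family: exactly 1
#'
#' @export
synonymousFrequencies <- function(x, code) {
  code <- .checkCode(code)
  if (is(x, "CodonUsageTable")) {
    vals <- cuValues(x)
  } else if (is.list(x) && !is.null(x$counts)) {
    vals <- x$counts
  } else if (is.numeric(x) && !is.null(names(x))) {
    vals <- x[CODONS]
    if (anyNA(vals)) stop("values must cover all 64 codons", call. = FALSE)
  } else {
    stop("'x' must be a CodonUsageTable, countCodons() result, ",
         "or named numeric vector", call. = FALSE)
  }
  if (any(vals < 0)) stop("negative codon value", call. = FALSE)
  if (sum(vals) == 0) stop("all-zero codon values", call. = FALSE)
  famTotals <- tapply(vals, code[names(vals)], sum)
  tot <- as.numeric(famTotals[code[names(vals)]])
  freq <- ifelse(tot > 0, vals / tot, NaN)
  names(freq) <- names(vals)
  new("SynonymousFrequencyTable", freq = freq, values = as.numeric(vals),
      code = code, codeId = attr(code, "tableId") %||% "")
}

#' G+C content of a coding sequence
#'
#' Overall and third-position G+C percentages, computed over complete,
#' unambiguous codons so that the metrics describe the same positions as
#' codon counting.
#'
#' @param seq A CDS (see \code{\link{countCodons}}).
#' @return Named numeric: \code{gcPercent}, \code{gc3Percent}.
#'
#' @examples
#' gcMetrics("ATGTCG")   # 50% overall, 100% at third positions
#'
#' @export
gcMetrics <- function(seq) {
  s <- .asCdsString(seq)
  codons <- .splitCodons(s)
  codons <- codons[!grepl("[^ACGT]", codons)]
  if (!length(codons)) return(c(gcPercent = NA_real_, gc3Percent = NA_real_))
  .gcFromCodons(codons)
}

.gcFromCodons <- function(codons) {
  nt <- strsplit(paste(codons, collapse = ""), "")[[1L]]
  gc <- mean(nt %in% c("G", "C")) * 100
  third <- substr(codons, 3L, 3L)
  gc3 <- mean(third %in% c("G", "C")) * 100
  c(gcPercent = gc, gc3Percent = gc3)
}

## Apply a pseudo-frequency to reference synonymous frequencies: codons with
## zero (or undefined) frequency receive eps and each family is renormalized
## to sum 1, preserving the table invariant.
.applyPseudoFreq <- function(reference, pseudoFreq) {
  freq <- reference@freq
  code <- reference@code
  vals <- stats::setNames(reference@values, names(freq))
  for (aa in unique(code)) {
    fam <- names(code)[code == aa]
    f <- freq[fam]
    if (!any(is.nan(f)) && all(f > 0)) next
    eps <- if (isTRUE(pseudoFreq)) {
      famTot <- sum(vals[fam])
      if (famTot > 0) 0.5 / famTot else 1 / length(fam)
    } else {
      as.numeric(pseudoFreq)
    }
    f[is.nan(f) | f == 0] <- eps
    freq[fam] <- f / sum(f)
  }
  new("SynonymousFrequencyTable", freq = freq, values = reference@values,
      code = code, codeId = reference@codeId)
}

#' Relative Codon Deoptimization Index of a gene
#'
#' Computes the RCDI of a coding sequence against a reference genome's
#' synonymous codon frequencies:
#' \deqn{RCDI = \sum_i \frac{CiFa_i}{CiFh_i} \cdot \frac{N_i}{N}}
#' where CiFa is the relative frequency of codon i within its synonymous
#' family in the test gene, CiFh the same quantity in the reference genome,
#' Ni the count of codon i in the gene and N the total counted codons.
#' RCDI is 1 when the gene's within-family codon usage matches the
#' reference exactly and grows with deoptimization, up to the inverse of
#' the smallest reference synonymous frequency among the codons used.
#'
#' CiFa is computed from the gene's own codon counts. Stop codons and
#' codons containing ambiguity characters are excluded from N (set
#' \code{includeStops = TRUE} to keep stops). A codon present in the gene
#' but with zero or undefined reference frequency is an error unless
#' \code{pseudoFreq} is given: \code{TRUE} replaces zeros with
#' 0.5/family-total (computed from the reference's raw values) and
#' renormalizes the family; a numeric value is used as the replacement
#' frequency directly.
#'
#' @param seq A CDS (see \code{\link{countCodons}}).
#' @param reference A \code{\linkS4class{SynonymousFrequencyTable}} built
#'   from the reference genome's codon usage, or a
#'   \code{\linkS4class{CodonUsageTable}} (converted with the same code).
#' @param code Genetic code map; defaults to the one stored in
#'   \code{reference}.
#' @param geneId Identifier recorded in the result.
#' @param includeStops Include stop codons in the computation.
#' @param pseudoFreq \code{NULL} (default: error on zero reference
#'   frequency), \code{TRUE}, or a replacement frequency.
#' @return An \code{\linkS4class{RcdiResult}}.
#'
#' @examples
#' code <- geneticCode(1)
#' ref <- synonymousFrequencies(
#'   codonUsageTable(stats::setNames(rep(1, 64), names(code))), code)
#' rcdiValue(rcdi("ATGATGATG", ref))   # single-codon family only: RCDI 1
#'
#' @export
rcdi <- function(seq, reference, code = NULL, geneId = "gene",
                 includeStops = FALSE, pseudoFreq = NULL) {
  if (is(reference, "CodonUsageTable")) {
    if (is.null(code))
      stop("supply 'code' when 'reference' is a CodonUsageTable", call. = FALSE)
    reference <- synonymousFrequencies(reference, code)
  }
  if (!is(reference, "SynonymousFrequencyTable"))
    stop("'reference' must be a SynonymousFrequencyTable or CodonUsageTable",
         call. = FALSE)
  code <- if (is.null(code)) reference@code else .checkCode(code)
  if (!identical(unname(code[CODONS]), unname(reference@code[CODONS])))
    stop("'code' disagrees with the genetic code of 'reference'",
         call. = FALSE)

  if (!is.null(pseudoFreq)) reference <- .applyPseudoFreq(reference, pseudoFreq)

  cc <- countCodons(seq, code, includeStops = includeStops)
  if (cc$total < 1L)
    stop(geneId, ": no countable codons", call. = FALSE)

  warnings <- character(0)
  if (cc$internalStops > 0L)
    warnings <- c(warnings,
                  sprintf("%d internal stop codon(s)", cc$internalStops))
  if (cc$excluded > 0L)
    warnings <- c(warnings,
                  sprintf("%d codon(s) excluded for ambiguity characters",
                          cc$excluded))

  cifa <- synonymousFrequencies(cc$counts, code)@freq
  cifh <- reference@freq
  present <- names(cc$counts)[cc$counts > 0L]
  badRef <- present[is.nan(cifh[present]) | cifh[present] == 0]
  if (length(badRef))
    stop(geneId, ": codon(s) absent from reference: ",
         paste(badRef, collapse = ", "),
         " (set 'pseudoFreq' to substitute a small frequency)", call. = FALSE)

  contrib <- stats::setNames(numeric(64L), CODONS)
  contrib[present] <- (cifa[present] / cifh[present]) * cc$counts[present]
  value <- sum(contrib) / cc$total

  gc <- .gcFromCodons(cc$codons)
  new("RcdiResult", geneId = as.character(geneId), rcdi = value,
      contributions = contrib, gcPercent = unname(gc[1L]),
      gc3Percent = unname(gc[2L]), nCodons = as.integer(cc$total),
      excludedCodons = as.integer(cc$excluded), warnings = warnings)
}

#' RCDI for a set of genes
#'
#' Applies \code{\link{rcdi}} to every sequence, computing CiFa per gene
#' (each gene is scored on its own codon usage).
#'
#' @param seqs Sequences: \code{DNAStringSet}, named character vector, or
#'   the result of \code{\link{readCds}}.
#' @param reference,code,includeStops,pseudoFreq As in \code{\link{rcdi}}.
#' @return Named list of \code{RcdiResult} objects.
#'
#' @export
computeRcdi <- function(seqs, reference, code = NULL,
                        includeStops = FALSE, pseudoFreq = NULL) {
  v <- .asCdsVector(seqs)
  out <- lapply(names(v), function(id)
    rcdi(v[[id]], reference, code = code, geneId = id,
         includeStops = includeStops, pseudoFreq = pseudoFreq))
  stats::setNames(out, names(v))
}

#' Tabulate RCDI results
#'
#' Flattens \code{RcdiResult} objects into the report layout: one row per
#' gene with \code{gene_id}, \code{n_codons}, \code{rcdi},
#' \code{gc_percent}, \code{gc3_percent} and, when
#' \code{contributions = TRUE}, one column per codon with the
#' (CiFa/CiFh)*Ni term.
#'
#' @param results An \code{RcdiResult} or list of them.
#' @param contributions Append the 64 per-codon contribution columns.
#' @return A \code{data.frame}.
#'
#' @export
rcdiTable <- function(results, contributions = TRUE) {
  if (is(results, "RcdiResult")) results <- list(results)
  stopifnot(all(vapply(results, is, logical(1L), "RcdiResult")))
  base <- data.frame(
    gene_id = vapply(results, geneId, character(1L)),
    n_codons = vapply(results, nCodons, integer(1L)),
    rcdi = vapply(results, rcdiValue, numeric(1L)),
    gc_percent = vapply(results, gcPercent, numeric(1L)),
    gc3_percent = vapply(results, gc3Percent, numeric(1L)),
    stringsAsFactors = FALSE
  )
  if (contributions) {
    mat <- t(vapply(results, function(r) r@contributions[CODONS],
                    numeric(64L)))
    colnames(mat) <- CODONS
    base <- cbind(base, as.data.frame(mat))
  }
  rownames(base) <- NULL
  base
}
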