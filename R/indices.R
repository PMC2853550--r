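#' CAI relative adaptiveness weights
#'
#' Builds the per-codon relative-adaptiveness table of the Codon Adaptation
#' Index from a reference codon-usage table: within each synonymous family,
#' \code{w = value / max(family values)}, so every family's preferred codon
#' has weight 1. Codons the reference never uses get, by the usual
#' convention, a small pseudo-weight of \code{0.5 / max(family values)}
#' when \code{pseudoCount = TRUE} (default); with \code{pseudoCount =
#' FALSE} they keep weight 0 and \code{\link{cai}} will refuse genes that
#' use them. Stop codons carry NA.
#'
#' @param x A \code{\linkS4class{CodonUsageTable}},
#'   \code{\linkS4class{SynonymousFrequencyTable}} or named numeric vector
#'   of per-codon values.
#' @param code Genetic code map.
#' @param pseudoCount Replace zero weights with 0.5/family-max.
#' @return A \code{\linkS4class{RelativeAdaptivenessTable}}.
#'
#' @export
caiWeights <- function(x, code, pseudoCount = TRUE) {
  code <- .checkCode(code)
  vals <- if (is(x, "CodonUsageTable")) cuValues(x)
          else if (is(x, "SynonymousFrequencyTable")) {
            v <- x@values; names(v) <- names(x@freq); v[CODONS]
          }
          else if (is.numeric(x) && !is.null(names(x))) x[CODONS]
          else stop("cannot extract codon values from 'x'", call. = FALSE)
  if (anyNA(vals)) stop("values must cover all 64 codons", call. = FALSE)
  w <- stats::setNames(rep(NA_real_, 64L), CODONS)
  for (aa in unique(code)) {
    if (aa == "*") next
    fam <- names(code)[code == aa]
    m <- max(vals[fam])
    if (m <= 0) { w[fam] <- NA_real_; next }       # family never used
    wf <- vals[fam] / m
    if (pseudoCount) wf[wf == 0] <- 0.5 / m
    w[fam] <- wf
  }
  new("RelativeAdaptivenessTable", w = w, code = code)
}

#' Codon Adaptation Index
#'
#' Geometric mean of the relative-adaptiveness weights of a gene's codons.
#' Stop codons and single-codon families (Met, Trp under the standard
#' code) are excluded from both the product and the exponent, following
#' the standard convention. CAI is 1 when the gene uses only each family's
#' preferred codon.
#'
#' @param seq A CDS.
#' @param weights A \code{\linkS4class{RelativeAdaptivenessTable}} from
#'   \code{\link{caiWeights}}.
#' @param code Genetic code map; defaults to the weights'.
#' @return CAI in (0, 1].
#'
#' @export
cai <- function(seq, weights, code = NULL) {
  stopifnot(is(weights, "RelativeAdaptivenessTable"))
  code <- if (is.null(code)) weights@code else .checkCode(code)
  cc <- countCodons(seq, code, includeStops = FALSE)
  famSize <- table(code[code != "*"])
  multi <- names(code)[code != "*" & famSize[code] > 1]
  counts <- cc$counts[intersect(names(cc$counts), multi)]
  counts <- counts[counts > 0]
  if (!length(counts)) stop("no codons from degenerate families", call. = FALSE)
  w <- weights@w[names(counts)]
  if (anyNA(w))
    stop("weights undefined for codon(s): ",
         paste(names(counts)[is.na(w)], collapse = ", "), call. = FALSE)
  if (any(w == 0))
    stop("zero weight for codon(s): ",
         paste(names(counts)[w == 0], collapse = ", "),
         "; rebuild weights with pseudoCount = TRUE", call. = FALSE)
  exp(sum(counts * log(w)) / sum(counts))
}

#' Effective Number of Codons (Wright's ENC)
#'
#' Reference-free measure of synonymous codon bias, from 20 (one codon per
#' amino acid, maximal bias) to 61 (uniform synonymous usage under the
#' standard code). Per-family codon homozygosity \eqn{\hat F = (n \sum
#' \hat p^2 - 1)/(n - 1)} is averaged within each degeneracy class
#' (2-, 3-, 4-, 6-fold), families observed fewer than 2 times are skipped,
#' and \deqn{ENC = n_1 + n_2/\bar F_2 + n_3/\bar F_3 + n_4/\bar F_4 +
#' n_6/\bar F_6} with class sizes taken from the genetic code (9/1/5/3
#' plus 2 single-codon families for the standard code). A missing or
#' degenerate 3-fold class average is imputed as the mean of the 2- and
#' 4-fold averages; any other missing class makes the ENC undefined. The
#' result is clipped at the code's number of sense codons.
#'
#' @param seq A CDS.
#' @param code Genetic code map.
#' @return ENC value in [20, 61] for the standard code.
#'
#' @export
enc <- function(seq, code) {
  code <- .checkCode(code)
  cc <- countCodons(seq, code, includeStops = FALSE)
  fams <- .families(code)
  fams <- fams[names(fams) != "*"]
  sizes <- lengths(fams)
  classSizes <- table(sizes)                      # families per degeneracy

  Fhat <- lapply(fams[sizes > 1L], function(cods) {
    n <- sum(cc$counts[cods])
    if (n < 2L) return(NULL)
    p <- cc$counts[cods] / n
    list(size = length(cods), F = (n * sum(p^2) - 1) / (n - 1))
  })
  Fhat <- Fhat[!vapply(Fhat, is.null, logical(1L))]
  if (!length(Fhat)) stop("ENC undefined: too few usable families", call. = FALSE)

  classes <- sort(unique(sizes[sizes > 1L]))
  Fbar <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (k in classes) {
    fk <- vapply(Fhat[vapply(Fhat, function(x) x$size == k, logical(1L))],
                 function(x) x$F, numeric(1L))
    if (length(fk)) Fbar[as.character(k)] <- mean(fk)
  }
  ## impute a missing/degenerate 3-fold class from its neighbours
  if ("3" %in% names(Fbar) && (is.na(Fbar[["3"]]) || Fbar[["3"]] <= 0)) {
    ok2 <- "2" %in% names(Fbar) && is.finite(Fbar[["2"]]) && Fbar[["2"]] > 0
    ok4 <- "4" %in% names(Fbar) && is.finite(Fbar[["4"]]) && Fbar[["4"]] > 0
    if (ok2 && ok4) Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  }
  if (anyNA(Fbar) || any(Fbar <= 0))
    stop("ENC undefined: missing degeneracy class ",
         paste(names(Fbar)[is.na(Fbar) | Fbar <= 0], collapse = ", "),
         call. = FALSE)

  n1 <- sum(sizes == 1L)
  value <- n1 + sum(as.numeric(classSizes[as.character(classes)]) / Fbar)
  min(value, sum(sizes))
}

#' Expected ENC from third-position G+C
#'
#' Wright's null expectation for the ENC of a gene whose synonymous codon
#' choice is driven purely by third-position composition:
#' \deqn{ENC_{exp}(s) = 2 + s + \frac{29}{s^2 + (1 - s)^2}}
#' with \code{s} the G+C fraction at third codon positions, strictly in
#' (0, 1). Symmetric about s = 0.5, where it peaks at 60.5.
#'
#' @param gc3 Third-position G+C fraction, strictly in (0, 1).
#' @return Expected ENC.
#'
#' @examples
#' expectedEnc(0.5)   # 60.5
#'
#' @export
expectedEnc <- function(gc3) {
  if (!is.numeric(gc3) || any(gc3 <= 0) || any(gc3 >= 1))
    stop("gc3 must lie strictly in (0, 1)", call. = FALSE)
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Companion codon-usage indices for a gene set
#'
#' Convenience wrapper computing, per gene: CAI against a reference table,
#' Wright's ENC, third-position %G+C and the expected ENC at that %G+C3.
#'
#' @param seqs Sequences.
#' @param reference A \code{CodonUsageTable} or
#'   \code{SynonymousFrequencyTable} for the CAI weights.
#' @param code Genetic code map.
#' @return \code{data.frame} with columns \code{gene_id}, \code{cai},
#'   \code{enc}, \code{gc3_percent}, \code{expected_enc}.
#'
#' @export
codonIndices <- function(seqs, reference, code) {
  code <- .checkCode(code)
  v <- .asCdsVector(seqs)
  w <- caiWeights(reference, code)
  rows <- lapply(names(v), function(id) {
    s <- v[[id]]
    gc3 <- unname(gcMetrics(s)["gc3Percent"]) / 100
    encVal <- tryCatch(enc(s, code), error = function(e) NA_real_)
    eenc <- if (gc3 > 0 && gc3 < 1) expectedEnc(gc3) else NA_real_
    data.frame(gene_id = id,
               cai = cai(s, w, code),
               enc = encVal,
               gc3_percent = gc3 * 100,
               expected_enc = eenc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
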