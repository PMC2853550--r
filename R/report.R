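#' Write the four-block analysis report
#'
#' Serializes RCDI (and optionally eRCDI) results into the four output
#' blocks of the analysis: (1) per-gene parameters — RCDI, the per-codon
#' (CiFa/CiFh)*Ni terms and %G+C; (2) global parameters — mean %G+C,
#' pooled amino-acid composition and the number of random sequences;
#' (3) statistical tests — KS normality of the random RCDIs and per-gene
#' chi-square homogeneity; (4) expected RCDI — mean and SD of the random
#' RCDIs and the eRCDI tolerance limit. Blocks 2-4 are marked absent when
#' no eRCDI result is supplied.
#'
#' @param results An \code{RcdiResult} or list of them.
#' @param ercdi Optional \code{\linkS4class{ErcdiResult}}.
#' @param indices Optional \code{data.frame} from
#'   \code{\link{codonIndices}}, merged into the gene block.
#' @param format \code{"tsv"} or \code{"json"}.
#' @param digits Decimal places for TSV display (half-even rounding);
#'   JSON output always carries full precision so it round-trips exactly.
#' @param file Optional path; when given the text is written there.
#' @return The report as a single character string (invisibly when
#'   \code{file} is given).
#'
#' @importFrom jsonlite toJSON
#' @importFrom utils write.table
#' @export
writeReport <- function(results, ercdi = NULL, indices = NULL,
                        format = c("tsv", "json"), digits = 4, file = NULL) {
  format <- match.arg(format)
  if (is(results, "RcdiResult")) results <- list(results)
  genes <- rcdiTable(results, contributions = TRUE)
  if (!is.null(indices))
    genes <- merge(genes, indices, by = "gene_id", sort = FALSE)

  warningsList <- lapply(results, function(r) r@warnings)
  names(warningsList) <- vapply(results, geneId, character(1L))

  if (!is.null(ercdi)) {
    stopifnot(is(ercdi, "ErcdiResult"))
    prof <- ercdi@profile
    global <- list(
      mean_gc_percent = prof@gcTarget * 100,
      mean_length_codons = prof@meanLengthCodons,
      n_sequences = length(results),
      n_random = ercdi@nRandom,
      aa_composition = as.list(prof@aaFreq)
    )
    tests <- list(
      ks_statistic = ercdi@ksStatistic,
      ks_pvalue_lilliefors = ercdi@ksPvalue,
      ks_pvalue_plain = ercdi@ksPlainPvalue,
      chi2_homogeneity = ercdi@chi2
    )
    expected <- list(
      random_rcdi_mean = ercdi@randomMean,
      random_rcdi_sd = ercdi@randomSd,
      tolerance_k = ercdi@k,
      ercdi = ercdi@ercdi,
      confidence = ercdi@config$confidence,
      coverage = ercdi@config$coverage,
      method = ercdi@config$method,
      seed = ercdi@config$seed,
      tolerance_method = ercdi@config$kMethod
    )
  } else {
    global <- tests <- expected <- NULL
  }

  text <- if (format == "json")
    .reportJson(genes, global, tests, expected, warningsList)
  else
    .reportTsv(genes, global, tests, expected, digits)

  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}

.reportJson <- function(genes, global, tests, expected, warningsList) {
  payload <- list(
    genes = genes,
    gene_warnings = warningsList[lengths(warningsList) > 0],
    global = global,
    tests = tests,
    expected_rcdi = expected
  )
  ## 17 significant digits: doubles survive the round-trip bit-for-bit
  as.character(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                                na = "null", null = "null", pretty = TRUE))
}

.roundDf <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

.tsvChunk <- function(df) {
  con <- textConnection("chunk", "w", local = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paste0(paste(chunk, collapse = "\n"), "\n")
}

.reportTsv <- function(genes, global, tests, expected, digits) {
  out <- character(0)
  out <- c(out, "## genes\n", .tsvChunk(.roundDf(genes, digits)))
  if (is.null(expected)) {
    out <- c(out, "## global\n# not computed (no eRCDI run)\n",
             "## statistical_tests\n# not computed (no eRCDI run)\n",
             "## expected_rcdi\n# not computed (no eRCDI run)\n")
    return(paste(out, collapse = ""))
  }
  gdf <- data.frame(mean_gc_percent = global$mean_gc_percent,
                    mean_length_codons = global$mean_length_codons,
                    n_sequences = global$n_sequences,
                    n_random = global$n_random)
  aadf <- as.data.frame(global$aa_composition, check.names = FALSE)
  out <- c(out, "## global\n", .tsvChunk(.roundDf(gdf, digits)),
           "# pooled amino-acid composition\n",
           .tsvChunk(.roundDf(aadf, digits)))
  tdf <- data.frame(ks_statistic = tests$ks_statistic,
                    ks_pvalue_lilliefors = tests$ks_pvalue_lilliefors,
                    ks_pvalue_plain = tests$ks_pvalue_plain)
  out <- c(out, "## statistical_tests\n", .tsvChunk(.roundDf(tdf, digits)))
  if (nrow(tests$chi2_homogeneity))
    out <- c(out, "# chi-square homogeneity (each gene vs pooled set)\n",
             .tsvChunk(.roundDf(tests$chi2_homogeneity, digits)))
  edf <- data.frame(random_rcdi_mean = expected$random_rcdi_mean,
                    random_rcdi_sd = expected$random_rcdi_sd,
                    tolerance_k = expected$tolerance_k,
                    ercdi = expected$ercdi,
                    confidence = expected$confidence,
                    coverage = expected$coverage,
                    method = expected$method,
                    seed = expected$seed %||% NA_integer_,
                    tolerance_method = expected$tolerance_method)
  out <- c(out, "## expected_rcdi\n", .tsvChunk(.roundDf(edf, digits)))
  paste(out, collapse = "")
}
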