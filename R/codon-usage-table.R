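#' Build or read a reference codon-usage table
#'
#' \code{codonUsageTable()} constructs a \code{\linkS4class{CodonUsageTable}}
#' from a named numeric vector of per-codon values;
#' \code{readCodonUsageTable()} parses the two tabular layouts codon-usage
#' databases distribute: the multi-codon-per-line layout
#' \code{"CODON per-thousand (count)"} (\code{dialect = "kazusa"}) and plain
#' \code{"CODON value"} lines (\code{dialect = "two_column"}). Codons may be
#' written with U or T.
#'
#' The scale is inferred when \code{scale = "auto"}: values summing to 1000
#' within 0.5 are frequencies per thousand, anything else is raw counts.
#' For the kazusa layout the parenthesized counts are used (and the scale is
#' \code{"counts"}) unless \code{scale = "per_thousand"} is requested
#' explicitly, in which case the per-thousand column is kept.
#'
#' @param values Named numeric vector with one value per codon (all 64).
#' @param scale \code{"auto"}, \code{"counts"} or \code{"per_thousand"}.
#' @param file,text Input table as a file path or a single string.
#' @param dialect \code{"auto"} (detect parentheses), \code{"kazusa"} or
#'   \code{"two_column"}.
#' @return A \code{CodonUsageTable}.
#'
#' @examples
#' vals <- stats::setNames(rep(100, 64), names(geneticCode(1)))
#' codonUsageTable(vals)             # counts (sum is 6400, not ~1000)
#'
#' @export
codonUsageTable <- function(values, scale = c("auto", "counts", "per_thousand")) {
  scale <- match.arg(scale)
  if (!is.numeric(values) || is.null(names(values)))
    stop("'values' must be a named numeric vector", call. = FALSE)
  nm <- .normalizeNt(names(values))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicated codon(s): ", paste(dup, collapse = ", "), call. = FALSE)
  missing <- setdiff(CODONS, nm)
  if (length(missing))
    stop("missing codon(s): ", paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(nm, CODONS)
  if (length(extra))
    stop("unknown codon(s): ", paste(extra, collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("codon values must be non-negative and non-missing", call. = FALSE)
  v <- as.numeric(values)
  names(v) <- nm
  v <- v[CODONS]
  if (scale == "auto")
    scale <- if (abs(sum(v) - 1000) <= 0.5) "per_thousand" else "counts"
  new("CodonUsageTable", values = v, scale = scale)
}

#' @rdname codonUsageTable
#' @export
readCodonUsageTable <- function(file = NULL, text = NULL,
                                dialect = c("auto", "kazusa", "two_column"),
                                scale = c("auto", "counts", "per_thousand")) {
  dialect <- match.arg(dialect)
  scale <- match.arg(scale)
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'", call. = FALSE)
  lines <- if (!is.null(file)) readLines(file, warn = FALSE)
           else strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty codon usage table", call. = FALSE)
  if (dialect == "auto")
    dialect <- if (any(grepl("\\(", lines))) "kazusa" else "two_column"

  if (dialect == "kazusa") {
    pat <- "([ACGTUacgtu]{3})\\s+([0-9]*\\.?[0-9]+)\\s*\\(\\s*([0-9]+)\\s*\\)"
    m <- regmatches(lines, gregexpr(pat, lines))
    hits <- do.call(rbind, lapply(m[lengths(m) > 0], function(x) {
      do.call(rbind, regmatches(x, regexec(pat, x)))
    }))
    if (is.null(hits))
      stop("no 'CODON freq (count)' entries found", call. = FALSE)
    codons <- hits[, 2L]
    vals <- if (scale == "per_thousand") as.numeric(hits[, 3L])
            else as.numeric(hits[, 4L])
    useScale <- if (scale == "per_thousand") "per_thousand" else "counts"
    return(codonUsageTable(stats::setNames(vals, codons), scale = useScale))
  }

  ## two_column: "CODON value" per line
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("cannot parse codon usage table line ", bad[1L], ": ",
         sQuote(trimws(lines[bad[1L]])), call. = FALSE)
  tab <- do.call(rbind, fields)
  vals <- suppressWarnings(as.numeric(tab[, 2L]))
  if (anyNA(vals))
    stop("non-numeric value for codon ", tab[which(is.na(vals))[1L], 1L],
         call. = FALSE)
  codonUsageTable(stats::setNames(vals, tab[, 1L]), scale = scale)
}
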