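#' Read coding sequences from FASTA
#'
#' Reads in-frame coding sequences (CDS) from a FASTA file or string.
#' Records may be multi-line, mixed case, DNA or RNA; sequences are
#' upper-cased and U is normalized to T. Identifiers are taken from the
#' header up to the first whitespace. Records that cannot be a CDS are not
#' silently dropped: they are returned in a \code{rejected} data frame with
#' a reason.
#'
#' A record is rejected when its length is not a positive multiple of 3
#' (unless \code{trimIncomplete = TRUE}, which trims 1-2 trailing
#' nucleotides with a warning) or when it contains characters outside the
#' IUPAC DNA alphabet. Ambiguity codes (N, R, Y, ...) are accepted here;
#' downstream codon counting excludes the codons that contain them.
#'
#' @param file Path to a FASTA file. Exactly one of \code{file}/\code{text}.
#' @param text FASTA content as a single string (convenience for scripts
#'   and tests).
#' @param trimIncomplete Trim, rather than reject, sequences with 1-2
#'   trailing nucleotides beyond the last complete codon.
#' @return A list with \code{sequences} (a named
#'   \code{\link[Biostrings]{DNAStringSet}} of accepted CDS) and
#'   \code{rejected} (data.frame with columns \code{id}, \code{reason}).
#'
#' @examples
#' res <- readCds(text = ">g1\natgTCGtaa\n>g2\nAUGUCG\n")
#' as.character(res$sequences)
#'
#' @importFrom Biostrings readBStringSet DNAStringSet
#' @export
readCds <- function(file = NULL, text = NULL, trimIncomplete = FALSE) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'", call. = FALSE)
  if (!is.null(text)) {
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
  }
  lines <- readLines(file, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty))
    stop("no sequences: input is empty", call. = FALSE)
  first <- nonEmpty[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("not FASTA: line ", first, " precedes the first '>' header",
         call. = FALSE)
  raw <- Biostrings::readBStringSet(file)
  if (!length(raw)) stop("no sequences", call. = FALSE)

  ids <- sub("\\s.*$", "", names(raw))
  seqs <- .normalizeNt(as.character(raw))
  keep <- logical(length(seqs))
  reasons <- character(0)
  rejIds <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    bad <- setdiff(unique(strsplit(s, "")[[1L]]), IUPAC_DNA)
    if (n == 0L) {
      rejIds <- c(rejIds, ids[i]); reasons <- c(reasons, "empty sequence")
    } else if (length(bad)) {
      rejIds <- c(rejIds, ids[i])
      reasons <- c(reasons, paste0("invalid character(s): ",
                                   paste(bad, collapse = ",")))
    } else if (n %% 3L != 0L) {
      if (trimIncomplete && n >= 3L) {
        warning("trimming ", n %% 3L, " trailing nt from ", ids[i],
                call. = FALSE)
        seqs[[i]] <- substr(s, 1L, n - n %% 3L)
        keep[i] <- TRUE
      } else {
        rejIds <- c(rejIds, ids[i])
        reasons <- c(reasons, "length not multiple of 3")
      }
    } else {
      keep[i] <- TRUE
    }
  }
  acc <- Biostrings::DNAStringSet(seqs[keep])
  names(acc) <- ids[keep]
  list(sequences = acc,
       rejected = data.frame(id = rejIds, reason = reasons,
                             stringsAsFactors = FALSE))
}

#' Write coding sequences to FASTA
#'
#' @param seqs Named character vector or \code{DNAStringSet}.
#' @param file Output path.
#' @return Invisibly, \code{file}.
#'
#' @importFrom Biostrings writeXStringSet DNAStringSet
#' @export
writeCdsFasta <- function(seqs, file) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
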