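#' Fetch a genetic code by NCBI translation-table id
#'
#' Returns the 64-codon map of an NCBI translation table as a named character
#' vector (codon -> one-letter amino acid, with \code{"*"} for stop codons).
#' Codes are taken from \pkg{Biostrings}, which ships every table the NCBI
#' taxonomy uses (1, 2, 3, 4, 5, 6, 9, 10, 11, ...).
#'
#' @param tableId Integer or character NCBI translation-table identifier.
#' @return Named character vector of length 64.
#'
#' @examples
#' geneticCode(1)[["ATG"]]   # "M"
#' geneticCode(1)[["TGA"]]   # "*"
#' geneticCode(2)[["TGA"]]   # "W" in the vertebrate mitochondrial code
#'
#' @importFrom Biostrings getGeneticCode GENETIC_CODE_TABLE
#' @export
geneticCode <- function(tableId = 1) {
  supported <- Biostrings::GENETIC_CODE_TABLE$id
  id <- as.character(tableId)
  if (length(id) != 1L || !(id %in% supported))
    stop("unsupported genetic code id ", sQuote(id), "; supported ids: ",
         paste(supported, collapse = ", "), call. = FALSE)
  code <- Biostrings::getGeneticCode(id)[CODONS]
  attr(code, "tableId") <- id
  code
}
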