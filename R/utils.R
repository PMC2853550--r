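## Internal codon bookkeeping shared across the package.

## Canonical codon order (TTT..GGG, as Biostrings lists them).
CODONS <- names(Biostrings::getGeneticCode("1"))

## G+C count of each codon (0..3), used by the matched-null sampler.
CODON_GC <- vapply(
  strsplit(CODONS, ""),
  function(x) sum(x %in% c("G", "C")),
  integer(1L)
)
names(CODON_GC) <- CODONS

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' @importFrom methods new is validObject slot show setMethod setClass setValidity
#' @importFrom stats sd setNames
NULL

## Normalize one nucleotide string: upper case, RNA U -> T.
.normalizeNt <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

## Coerce a sequence argument (character scalar, DNAString, or a length-1
## XStringSet element) to a validated CDS string. Ambiguity codes are allowed
## here; frame and alphabet are enforced.
.asCdsString <- function(seq, what = "seq") {
  if (is(seq, "XString") || is(seq, "XStringSet")) {
    if (is(seq, "XStringSet")) {
      if (length(seq) != 1L)
        stop(what, " must be a single sequence; got ", length(seq), call. = FALSE)
      seq <- seq[[1L]]
    }
    seq <- as.character(seq)
  }
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single nucleotide string", call. = FALSE)
  s <- .normalizeNt(seq)
  n <- nchar(s)
  if (n == 0L || n %% 3L != 0L)
    stop(what, ": length ", n, " is not a positive multiple of 3", call. = FALSE)
  bad <- setdiff(unique(strsplit(s, "")[[1L]]), IUPAC_DNA)
  if (length(bad))
    stop(what, ": invalid character(s) ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  s
}

## Split a validated CDS string into its codons (in order).
.splitCodons <- function(s) {
  n <- nchar(s)
  substring(s, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

## Coerce a collection of sequences (XStringSet, character vector, list, or
## the $sequences element of readCds()) to a named character vector of CDS.
.asCdsVector <- function(seqs) {
  if (is.list(seqs) && !is.null(seqs$sequences)) seqs <- seqs$sequences
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is(seqs, "XString")) seqs <- as.character(seqs)
  if (is.list(seqs)) seqs <- unlist(seqs, use.names = TRUE)
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("no sequences supplied", call. = FALSE)
  nm <- names(seqs)
  if (is.null(nm)) nm <- rep("", length(seqs))
  nm[!nzchar(nm)] <- paste0("seq_", which(!nzchar(nm)))
  names(seqs) <- nm
  out <- vapply(seq_along(seqs),
                function(i) .asCdsString(seqs[[i]], what = nm[i]),
                character(1L), USE.NAMES = FALSE)
  names(out) <- names(seqs)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Validate that `code` is a 64-codon genetic code map.
.checkCode <- function(code) {
  if (!is.character(code) || length(code) != 64L ||
      is.null(names(code)) || !setequal(names(code), CODONS))
    stop("'code' must be a 64-codon genetic code map; see geneticCode()",
         call. = FALSE)
  code[CODONS]
}

## Synonymous families of a genetic code: named list amino acid -> codons.
## Stop codons form their own family "*".
.families <- function(code) {
  code <- .checkCode(code)
  split(names(code), code)
}
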