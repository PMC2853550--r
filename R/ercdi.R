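#' Composition profile of a query set
#'
#' Summarizes one or more coding sequences by the quantities the
#' expected-RCDI null is matched to: amino-acid composition pooled over all
#' counted codons (weighted by gene length, i.e. the composition of the
#' concatenated input), pooled G+C fraction, and rounded mean length in
#' codons. A first-order amino-acid transition matrix is also estimated
#' from the concatenated translations for the Markov generator; rows
#' without observed transitions fall back to the pooled composition.
#'
#' Stop codons and ambiguous codons are excluded throughout, so the
#' profile describes exactly the codons that enter the RCDI.
#'
#' @param seqs Sequences (\code{DNAStringSet}, named character vector, or
#'   \code{\link{readCds}} output).
#' @param code Genetic code map from \code{\link{geneticCode}}.
#' @return A \code{\linkS4class{CompositionProfile}}.
#'
#' @examples
#' p <- compositionProfile(c(g = strrep("ATG", 10)), geneticCode(1))
#' aaFreq(p)          # all Met
#' meanLengthCodons(p)
#'
#' @export
compositionProfile <- function(seqs, code) {
  code <- .checkCode(code)
  v <- .asCdsVector(seqs)
  if (!length(v)) stop("empty input: no sequences", call. = FALSE)
  perGene <- lapply(v, countCodons, code = code, includeStops = FALSE)
  totals <- vapply(perGene, function(x) as.numeric(x$total), numeric(1L))
  if (any(totals < 1)) stop("a sequence has no countable codons", call. = FALSE)

  aas <- sort(unique(code[code != "*"]))
  pooled <- stats::setNames(numeric(length(aas)), aas)
  gcNum <- 0; ntNum <- 0
  transitions <- matrix(0, length(aas), length(aas),
                        dimnames = list(aas, aas))
  for (cc in perGene) {
    aaCounts <- tapply(cc$counts, code[names(cc$counts)], sum)
    aaCounts <- aaCounts[names(aaCounts) != "*"]
    pooled[names(aaCounts)] <- pooled[names(aaCounts)] + aaCounts
    gcNum <- gcNum + sum(CODON_GC[cc$codons])
    ntNum <- ntNum + 3L * length(cc$codons)
    aaSeq <- unname(code[cc$codons])
    if (length(aaSeq) >= 2L) {
      tt <- table(factor(aaSeq[-length(aaSeq)], levels = aas),
                  factor(aaSeq[-1L], levels = aas))
      transitions <- transitions + unclass(tt)
    }
  }
  aaFreq <- pooled / sum(pooled)
  rs <- rowSums(transitions)
  P <- transitions
  for (a in aas) {
    P[a, ] <- if (rs[a] > 0) transitions[a, ] / rs[a] else aaFreq
  }
  new("CompositionProfile",
      aaFreq = aaFreq,
      gcTarget = gcNum / ntNum,
      meanLengthCodons = as.integer(round(mean(totals))),
      aaTransitions = P)
}

## Per-family codon info for the GC-weighted sampler: codons and their
## G+C counts, restricted to amino acids present in the profile.
.samplerFamilies <- function(profile, code) {
  aas <- names(profile@aaFreq)[profile@aaFreq > 0]
  fams <- .families(code)
  lapply(stats::setNames(aas, aas), function(a) {
    cods <- fams[[a]]
    list(codons = cods, gc = CODON_GC[cods])
  })
}

## Expected overall G+C fraction under codon probabilities p_c(w) ~ w^gc_c.
.expectedGc <- function(logw, profile, fams) {
  aaf <- profile@aaFreq[names(fams)]
  e <- vapply(fams, function(f) {
    lp <- f$gc * logw
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    sum(p * f$gc) / 3
  }, numeric(1L))
  sum(aaf * e)
}

#' Achievable G+C interval of a composition profile
#'
#' The minimum and maximum overall G+C fraction reachable by synonymous
#' codon choice alone, given the profile's amino-acid composition.
#'
#' @param profile A \code{CompositionProfile}.
#' @param code Genetic code map.
#' @return Numeric of length 2: \code{c(min, max)}.
#'
#' @export
achievableGc <- function(profile, code) {
  code <- .checkCode(code)
  fams <- .samplerFamilies(profile, code)
  aaf <- profile@aaFreq[names(fams)]
  lo <- sum(aaf * vapply(fams, function(f) min(f$gc), numeric(1L)) / 3)
  hi <- sum(aaf * vapply(fams, function(f) max(f$gc), numeric(1L)) / 3)
  c(lo, hi)
}

#' Solve the G+C weight of the matched-null codon sampler
#'
#' The random-sequence generator draws each synonymous codon with
#' probability proportional to \code{w^gc}, where \code{gc} is the codon's
#' G+C count. This solves for the \code{w > 0} that makes the expected
#' overall G+C fraction of a generated sequence equal the profile's
#' \code{gcTarget}, by monotone bisection on \code{log(w)} (the expectation
#' is strictly increasing in \code{w} whenever any family has codons of
#' unequal G+C).
#'
#' @param profile A \code{CompositionProfile}.
#' @param code Genetic code map.
#' @param tol Tolerance on the expected G+C fraction.
#' @return The weight \code{w} (1 when the target equals the unweighted
#'   expectation).
#'
#' @export
gcWeightSolve <- function(profile, code, tol = 1e-10) {
  code <- .checkCode(code)
  fams <- .samplerFamilies(profile, code)
  rng <- achievableGc(profile, code)
  target <- profile@gcTarget
  if (target <= rng[1L] + tol || target >= rng[2L] - tol)
    stop(sprintf(paste0("gcTarget %.4f is not strictly inside the achievable",
                        " G+C interval [%.4f, %.4f]"),
                 target, rng[1L], rng[2L]), call. = FALSE)
  f <- function(lw) .expectedGc(lw, profile, fams) - target
  lo <- -1; hi <- 1
  while (f(lo) > 0) { lo <- lo * 2; if (lo < -700) break }
  while (f(hi) < 0) { hi <- hi * 2; if (hi > 700) break }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(exp(mid))
    if (fm < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-14) break
  }
  exp((lo + hi) / 2)
}

## Per-family codon sampling probabilities for a given weight (or at a GC
## boundary: uniform over the family's min- or max-GC codons).
.codonProbs <- function(fams, w = NULL, boundary = NULL) {
  lapply(fams, function(f) {
    if (!is.null(boundary)) {
      extreme <- if (boundary == "min") f$gc == min(f$gc) else f$gc == max(f$gc)
      p <- as.numeric(extreme) / sum(extreme)
    } else {
      lp <- f$gc * log(w)
      p <- exp(lp - max(lp))
      p <- p / sum(p)
    }
    stats::setNames(p, f$codons)
  })
}

#' Generate random coding sequences matched to a composition profile
#'
#' Draws random CDS whose amino-acid composition and expected G+C fraction
#' match a \code{\linkS4class{CompositionProfile}}; these form the null set
#' from which the expected RCDI is computed. Two generation methods:
#' \describe{
#'   \item{poisson}{each codon independent — the amino acid is sampled from
#'     the profile's composition, then a synonymous codon from the
#'     GC-weighted sampler (see \code{\link{gcWeightSolve}});}
#'   \item{markov}{amino acids follow the first-order chain estimated from
#'     the queries (initial state from the pooled composition), codons
#'     chosen as above.}
#' }
#' No stop codons are emitted. When the target G+C sits on the boundary of
#' the achievable interval the extreme codon of each family is used;
#' outside the interval is an error.
#'
#' @param profile A \code{CompositionProfile}.
#' @param code Genetic code map.
#' @param n Number of sequences.
#' @param method \code{"poisson"} or \code{"markov"}.
#' @param lengthCodons Length of each sequence in codons; default the
#'   profile's mean input length.
#' @return A \code{DNAStringSet} named \code{random_1 ... random_n}.
#'
#' @export
generateRandomCds <- function(profile, code, n = 1L,
                              method = c("poisson", "markov"),
                              lengthCodons = NULL) {
  method <- match.arg(method)
  code <- .checkCode(code)
  stopifnot(is(profile, "CompositionProfile"), n >= 1L)
  L <- as.integer(lengthCodons %||% profile@meanLengthCodons)
  if (L < 1L) stop("lengthCodons must be >= 1", call. = FALSE)

  fams <- .samplerFamilies(profile, code)
  rng <- achievableGc(profile, code)
  target <- profile@gcTarget
  btol <- 1e-9
  if (target < rng[1L] - btol || target > rng[2L] + btol)
    stop(sprintf(paste0("gcTarget %.4f outside the achievable G+C interval ",
                        "[%.4f, %.4f] for this amino-acid composition"),
                 target, rng[1L], rng[2L]), call. = FALSE)
  probs <- if (rng[2L] - rng[1L] < btol) {
    .codonProbs(fams, w = 1)                      # no degeneracy in GC
  } else if (target <= rng[1L] + btol) {
    .codonProbs(fams, boundary = "min")
  } else if (target >= rng[2L] - btol) {
    .codonProbs(fams, boundary = "max")
  } else {
    .codonProbs(fams, w = gcWeightSolve(profile, code))
  }

  aas <- names(fams)
  aaf <- profile@aaFreq[aas]
  aaf <- aaf / sum(aaf)

  drawAa <- function() {
    if (method == "poisson") {
      matrix(sample(aas, n * L, replace = TRUE, prob = aaf), nrow = n)
    } else {
      P <- profile@aaTransitions[aas, aas, drop = FALSE]
      P <- sweep(pmax(P, 0), 1L, pmax(rowSums(pmax(P, 0)), .Machine$double.eps),
                 "/")
      m <- matrix("", n, L)
      m[, 1L] <- sample(aas, n, replace = TRUE, prob = aaf)
      if (L >= 2L) for (t in 2L:L) {
        cur <- m[, t - 1L]
        for (a in unique(cur)) {
          idx <- which(cur == a)
          m[idx, t] <- sample(aas, length(idx), replace = TRUE, prob = P[a, ])
        }
      }
      m
    }
  }
  aaMat <- drawAa()
  codMat <- matrix("", n, L)
  for (a in aas) {
    idx <- which(aaMat == a)
    if (!length(idx)) next
    p <- probs[[a]]
    codMat[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
  }
  out <- Biostrings::DNAStringSet(apply(codMat, 1L, paste, collapse = ""))
  names(out) <- paste0("random_", seq_len(n))
  out
}

#' One-sided normal tolerance factor
#'
#' The factor \code{k} such that \code{mean + k*sd} of a normal sample of
#' size \code{n} exceeds the population's \code{coverage} quantile with
#' probability \code{confidence}. Computed exactly from the noncentral-t
#' distribution: \code{k = qt(confidence, df = n-1,
#' ncp = qnorm(coverage)*sqrt(n)) / sqrt(n)}. If the noncentral quantile is
#' not finite (extreme arguments), Howe's closed-form approximation is used
#' and recorded in the \code{"method"} attribute.
#'
#' @param n Sample size (>= 2).
#' @param confidence,coverage Probabilities in (0, 1).
#' @return \code{k}, with attribute \code{"method"} set to
#'   \code{"noncentral_t"} or \code{"howe"}.
#'
#' @examples
#' toleranceFactor(50, 0.95, 0.99)
#'
#' @importFrom stats qt qnorm
#' @export
toleranceFactor <- function(n, confidence = 0.95, coverage = 0.99) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("'n' must be a single number >= 2", call. = FALSE)
  for (p in c(confidence, coverage))
    if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
      stop("confidence and coverage must lie strictly in (0, 1)", call. = FALSE)
  ncp <- qnorm(coverage) * sqrt(n)
  k <- suppressWarnings(qt(confidence, df = n - 1, ncp = ncp) / sqrt(n))
  method <- "noncentral_t"
  if (!is.finite(k)) {
    zc <- qnorm(coverage); zb <- qnorm(confidence)
    a <- 1 - zb^2 / (2 * (n - 1))
    b <- zc^2 - zb^2 / n
    k <- (zc + sqrt(pmax(zc^2 - a * b, 0))) / a
    method <- "howe"
  }
  attr(k, "method") <- method
  k
}

#' Expected RCDI of a query set
#'
#' Builds the composition profile of the queries, generates \code{nRandom}
#' random coding sequences matched to it, computes the RCDI of each against
#' the reference, and returns the expected RCDI
#' \deqn{eRCDI = \bar{x} + k \cdot s}
#' where \code{x} are the random RCDIs, \code{s} their sample SD (n-1
#' denominator) and \code{k} the one-sided normal tolerance factor for the
#' requested confidence and coverage. A query RCDI above the eRCDI exceeds
#' what G+C and amino-acid composition alone explain.
#'
#' Also runs the server's statistical checks: a Kolmogorov-Smirnov
#' normality test (Lilliefors corrected) of the random RCDI distribution,
#' and per-query chi-square homogeneity tests of amino-acid composition and
#' G+C (each query against the pooled set; requires >= 2 queries, otherwise
#' the chi-square block is empty).
#'
#' @param seqs Query sequences.
#' @param reference \code{SynonymousFrequencyTable} (or
#'   \code{CodonUsageTable} with \code{code}).
#' @param code Genetic code map; defaults to the reference's.
#' @param nRandom Number of random sequences (>= 2; >= 8 for the KS test).
#' @param method Random-generation method, \code{"poisson"} or
#'   \code{"markov"}.
#' @param confidence,coverage Tolerance-limit parameters in (0, 1).
#' @param seed Integer seed; fixing it makes the result fully reproducible.
#' @param lengthCodons \code{"mean_of_inputs"} (default) or an integer
#'   length for the random sequences.
#' @param pseudoFreq Passed to \code{\link{rcdi}} for the random sequences
#'   (useful when the reference lacks some codons).
#' @return An \code{\linkS4class{ErcdiResult}}.
#'
#' @export
expectedRcdi <- function(seqs, reference, code = NULL, nRandom = 500L,
                         method = c("poisson", "markov"),
                         confidence = 0.95, coverage = 0.99, seed = NULL,
                         lengthCodons = "mean_of_inputs", pseudoFreq = NULL) {
  method <- match.arg(method)
  if (nRandom < 2L) stop("nRandom must be >= 2", call. = FALSE)
  if (is(reference, "CodonUsageTable")) {
    if (is.null(code))
      stop("supply 'code' when 'reference' is a CodonUsageTable", call. = FALSE)
    reference <- synonymousFrequencies(reference, code)
  }
  code <- if (is.null(code)) reference@code else .checkCode(code)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }

  v <- .asCdsVector(seqs)
  profile <- compositionProfile(v, code)
  L <- if (identical(lengthCodons, "mean_of_inputs"))
    profile@meanLengthCodons else as.integer(lengthCodons)
  rand <- generateRandomCds(profile, code, n = nRandom, method = method,
                            lengthCodons = L)
  vals <- vapply(seq_len(nRandom), function(i)
    rcdi(as.character(rand[[i]]), reference, code = code,
         geneId = names(rand)[i], pseudoFreq = pseudoFreq)@rcdi,
    numeric(1L))

  m <- mean(vals)
  s <- stats::sd(vals)
  k <- toleranceFactor(nRandom, confidence, coverage)
  ercdi <- m + as.numeric(k) * s

  if (nRandom >= 8L && s > 0) {
    ks <- ksNormality(vals)
  } else {
    ks <- list(statistic = NA_real_, pvalue = NA_real_,
               plainPvalue = NA_real_)
  }
  chi2 <- if (length(v) >= 2L) chi2Homogeneity(v, code) else
    data.frame(gene_id = character(0), aa_statistic = numeric(0),
               aa_df = integer(0), aa_pvalue = numeric(0),
               gc_statistic = numeric(0), gc_pvalue = numeric(0),
               stringsAsFactors = FALSE)

  new("ErcdiResult", randomRcdi = vals, randomMean = m, randomSd = s,
      k = as.numeric(k), ercdi = ercdi,
      ksStatistic = ks$statistic, ksPvalue = ks$pvalue,
      ksPlainPvalue = ks$plainPvalue, chi2 = chi2, profile = profile,
      nRandom = as.integer(nRandom),
      config = list(method = method, confidence = confidence,
                    coverage = coverage, seed = seed,
                    lengthCodons = L, kMethod = attr(k, "method")))
}
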