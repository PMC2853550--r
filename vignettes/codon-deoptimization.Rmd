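---
title: "Measuring codon usage deoptimization: RCDI, eRCDI and companions"
author: "codonDeopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring codon usage deoptimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonDeopt)
```

## The index

A coding sequence read in frame is a multiset of codons. Within each
synonymous family (the codons encoding one amino acid under a given
genetic code), relative frequencies can be compared between a test gene
and a reference genome. The Relative Codon Deoptimization Index is

$$\mathrm{RCDI} \;=\; \sum_i \frac{C_iF_a}{C_iF_h}\cdot\frac{N_i}{N},$$

with $C_iF_a$ the within-family relative frequency of codon $i$ in the
test gene, $C_iF_h$ the same quantity in the reference, $N_i$ the codon's
count and $N$ the total counted codons. Because both $C_iF_a$ and
$C_iF_h$ are probability vectors within each family, the per-family sum
$\sum_i C_iF_a^2/C_iF_h$ is minimized exactly when the two vectors
coincide (Cauchy–Schwarz), so RCDI $\ge 1$ with equality iff the gene's
family-wise usage matches the reference; the attainable maximum is the
inverse of the smallest reference frequency among the codons the gene
uses. Both properties are enforced as property-style tests.

Conventions, all overridable:

* **$C_iF_a$ is computed per gene**, from the gene's own counts. When
  several genes are submitted each is scored independently (pooling the
  set before computing $C_iF_a$ would let long genes mask short ones).
* **Stop codons are excluded** from $N$ and from family normalization
  (`includeStops = TRUE` restores them). Normalizing a "stop family" is
  meaningless for a single-ORF gene with one terminal stop; an *internal*
  stop is reported as a per-gene warning and computation proceeds.
* **Ambiguity codons are excluded and tallied**, and %G+C / %G+C₃ are
  computed over exactly the counted codons, so every reported gene
  parameter describes the same positions.
* A codon used by the gene but absent from the reference leaves the index
  undefined; this errors by default. `pseudoFreq = TRUE` substitutes
  $0.5/\text{family total}$ (or any user value) and renormalizes the
  family, which keeps the within-family frequencies a probability vector
  and therefore preserves the RCDI $\ge 1$ bound.
* The per-codon report column is the product $(C_iF_a/C_iF_h)\cdot N_i$ —
  the summand of the defining sum before division by $N$ — not a power;
  the notation is ambiguous in print, the product is what sums back to
  $N\cdot\mathrm{RCDI}$.

## The expected RCDI

Composition alone moves the RCDI: a gene rich in amino acids whose
host-preferred codons are GC-rich will look "deoptimized" merely by being
AT-rich. The eRCDI therefore builds a matched null. From the query set we
take a `CompositionProfile`: amino-acid frequencies pooled over all
counted codons (i.e. of the concatenated input — pooling weighted by gene
length; a per-gene mean would overweight short genes), the pooled G+C
fraction, and the rounded mean length in codons.

Random coding sequences are drawn to match the profile:

* **poisson** — codons i.i.d.: amino acid from the pooled frequencies,
  then a synonymous codon with probability $\propto w^{g_c}$, where $g_c$
  is the codon's G+C count and $w$ solves
  $\mathbb{E}[\text{G+C fraction}](w) = \text{target}$.
* **markov** — amino acids follow a first-order chain whose transition
  matrix is estimated from the concatenated query translations (rows
  without observations fall back to the pooled frequencies); codons as
  above.

The weight exponent uses the codon's *total* G+C count; weighting only
the degenerate positions gives identical sampling probabilities, because
positions shared by a whole family contribute a common factor that
cancels in the normalization. The expectation is available in closed form
from the profile and the per-family codon G+C counts; it is strictly
increasing in $w$, and we solve it by bisection on $\log w$ to $10^{-10}$
on the expected G+C. Targets on the boundary of the achievable interval
(e.g. an all-Phe profile at its maximum G+C of 1/3) switch to the
extreme codon of each family; targets outside it are an error that
reports the interval. No stop codons are ever emitted, so every random
sequence is a valid single-ORF CDS.

Whether the original server's "Poisson" and "Markov" operate on
nucleotides or codons is not recoverable from its description; the
codon-level definition used here is our interpretation, chosen because it
matches composition by construction and is directly testable (the suite
checks total-variation convergence of the amino-acid composition and
3-standard-error agreement of mean G+C).

From the $n$ random RCDIs the eRCDI is the one-sided normal tolerance
limit

$$\mathrm{eRCDI} = \bar{x} + k\, s, \qquad
k = \frac{t^{-1}_{n-1,\; z_{\text{cov}}\sqrt{n}}(\text{conf})}{\sqrt{n}},$$

with $s$ the $n-1$ sample SD (the tolerance-limit derivation assumes it)
and $k$ the exact noncentral-$t$ factor; Howe's approximation is used
only if the noncentral quantile is not finite, and the choice is recorded
in the result. With confidence and coverage both 0.5, $k = 0$ and the
limit degenerates to the mean; it increases strictly in both parameters.
Note the convergence $k \to z_{\text{cov}}$ is slow,
$k \approx z_{\text{cov}} + z_{\text{conf}}\sqrt{(1 + z_{\text{cov}}^2/2)/n}$,
so even at $n = 10^6$ the factor for (0.95, 0.99) still sits
$\approx 3\times10^{-3}$ above $z_{0.99}$.

Defaults: `nRandom = 500`, `confidence = 0.95`, `coverage = 0.99`,
`method = "poisson"`, random length = rounded mean input length. The
number of random sequences and the length rule are user choices the
original tool also leaves open; 500 makes the SD of the estimated mean
about 4% of the null SD while keeping a full run interactive.

## Statistical checks

The tolerance limit assumes the random RCDIs are roughly normal. We test
this with a one-sample Kolmogorov–Smirnov statistic against
$\mathcal{N}(\bar x, s)$; since the parameters are estimated from the
same sample, the honest p-value is the Lilliefors-corrected one
(`nortest::lillie.test`), which the suite shows holds its 5% level; the
uncorrected KS p is also reported for comparison with tools that skip the
correction. In practice short random sequences give a right-skewed null
(RCDI is bounded below by 1) and the KS test flags it — that is the
diagnostic working, and a cue to read the eRCDI as approximate.

The eRCDI is only meaningful if the queries share a composition. Each
query is therefore compared against the pooled set with chi-square
goodness-of-fit tests: amino-acid counts against expectations from the
pooled frequencies (categories with expected count < 1 are pooled into
one; df = remaining categories − 1), and G+C vs A+T nucleotide counts
against the pooled G+C fraction (df = 1). Each-versus-pooled was chosen
over all pairwise comparisons to keep one row per gene and avoid a
quadratic multiple-testing burden. Identical sequences give statistic 0
and p = 1 exactly; a single query cannot be tested (the functions demand
two, and `expectedRcdi()` then simply leaves the block empty).

## Companion indices

* **CAI** (Sharp & Li conventions): geometric mean of per-codon relative
  adaptiveness $w = f/f_{\max}$ within families, excluding stops and
  single-codon families from the exponent. Codons unused by the reference
  get $w = 0.5/f_{\max}$ when pseudo-counting is on (default); with it
  off they keep $w = 0$ and `cai()` refuses genes that use them.
* **ENC** (Wright's procedure): per-family homozygosity
  $\hat F = (n\sum\hat p^2 - 1)/(n-1)$, averaged within degeneracy
  classes, $ENC = n_1 + n_2/\bar F_2 + n_3/\bar F_3 + n_4/\bar F_4 +
  n_6/\bar F_6$ with class sizes taken from the genetic code (2, 9, 1, 5,
  3 for the standard code), families observed fewer than twice skipped, a
  missing 3-fold class imputed as the mean of the 2- and 4-fold averages,
  and the result clipped at the number of sense codons (61).
* **Expected ENC** from third-position G+C:
  $2 + s + 29/(s^2 + (1-s)^2)$, $s \in (0,1)$. The curve peaks at
  $s = 0.5$ (60.5) and falls toward both extremes; the linear term makes
  it slightly asymmetric (38.27 at $s=0.9$ vs 37.47 at $s=0.1$), a
  property of the published formula itself.

CAI and RCDI are deliberately different optima: CAI = 1 needs a gene of
only family-preferred codons, RCDI = 1 needs the gene to *reproduce the
reference mix*, rare codons included. The suite constructs genes that are
extremal for one and not the other. On synthetic gene sets ENC correlates
with RCDI (both respond to usage bias) while CAI does so only weakly —
the qualitative pattern expected from their definitions; we make no
quantitative claim about real viral genomes, which would require external
sequence data.

## Synthetic data and what passing tests mean

Every fixture is generated in code: reference tables with engineered
family frequencies (e.g. a Ser family at exactly 567/10000 for TCG, the
classic human-genome landmark whose inverse, 17.64, the worked example
reproduces), random strictly-positive usage tables, random genes, and
matched gene/reference pairs that realize rational family frequencies
exactly (these must give RCDI = 1 to within $10^{-9}$). The null
generator itself doubles as the simulator for calibration tests. What
this emulates well: composition-driven codon usage, frame-correct CDS,
reference tables of both scales. What it does not: codon-pair and
dinucleotide biases, CpG suppression, local GC gradients along a gene,
and selection on translation kinetics — so green tests validate the
index arithmetic and the null's calibration, not any biological claim
about a particular virus.

Problem sizes in the default suite were chosen to make sampling error
negligible relative to the asserted tolerances while keeping a full run
under a minute: 100 matched constructions, 1000 random gene/reference
pairs for the bounds, a $10^5$-codon sequence for composition
convergence (TV < 0.05), 1000 sequences for G+C convergence (3 SE), 500
replicates for tolerance-limit coverage and 200 seeds for KS
calibration.

## Numerical choices and degenerate inputs

* Family frequencies of unobserved families are `NaN` ("undefined"),
  never 0 — a zero frequency is information, an undefined one is absence.
* TSV display rounds half-even at 4 decimals by default; JSON reports
  serialize at 17 significant digits so `fromJSON()` reproduces every
  double bit-for-bit; internal computation is always full precision.
* All randomness flows through R's global RNG; `expectedRcdi(seed =)`
  saves and restores `.Random.seed`, so a seeded call is reproducible
  and side-effect free. Identical seed + inputs give byte-identical JSON
  reports.
* Sequences are validated before counting: length a positive multiple of
  3 (no silent truncation — `trimIncomplete` is an explicit opt-in that
  warns), IUPAC alphabet, U→T. Rejections are returned with reasons, not
  dropped.
* Degenerate requests fail loudly: empty FASTA, tables with missing or
  duplicated codons, all-zero tables, a constant sample in the KS test,
  fewer than 8 values for KS, a single sequence for homogeneity, GC
  targets outside the achievable interval, ENC with too few usable
  families.

## Limitations

The eRCDI is a *normal* tolerance limit over a distribution that is
bounded below and can be skewed for short sequences; the KS diagnostic
reports when this bites, but the limit itself is not corrected (an
empirical-quantile variant is deliberately out of scope). The null
matches global composition only — no GC3-specific or positional
matching. The chi-square homogeneity tests are asymptotic; for very
short genes the amino-acid test relies on the expected<1 pooling rule.
Genetic codes are limited to the NCBI translation tables shipped with
Biostrings (all current ones).
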