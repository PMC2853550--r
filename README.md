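# codonDeopt

Codon usage deoptimization indices for coding sequences: the **Relative
Codon Deoptimization Index (RCDI)** with its significance threshold, the
**expected RCDI (eRCDI)**, plus the companion indices CAI, ENC, expected
ENC and %G+C₃.

## The problem

Viral genes are translated by the host's tRNA pool, so their synonymous
codon usage relative to the host carries a signal: usage close to the host
reference suggests adaptation (high translation rates, as in lytic
viruses), while systematic use of host-rare codons — *deoptimization* — is
seen in viruses with low replication rates and is engineered deliberately
in attenuated vaccine candidates. The same comparison is useful whenever a
gene is expressed in a heterologous host.

The RCDI quantifies this for a gene against a reference genome's codon
usage table:

```
RCDI = Σ_i (CiFa_i / CiFh_i) · N_i / N
```

where `CiFa_i` is the relative frequency of codon *i* within its
synonymous (same amino acid) family in the test gene, `CiFh_i` the same
quantity in the reference genome, `N_i` the codon's count in the gene, and
`N` the total number of counted codons. RCDI = 1 when the gene's
within-family codon usage matches the reference exactly, and grows with
deoptimization up to `1 / min CiFh` over the codons used (for a human-like
reference the extreme is a pure-TCG sequence, RCDI ≈ 17.64).

A raw RCDI is confounded by G+C content and amino-acid composition. The
eRCDI calibrates it: random coding sequences are generated with the *same*
amino-acid composition and expected G+C as the queries (i.i.d. "poisson"
codons or a first-order amino-acid "markov" chain, with a GC-weighted
synonymous-codon sampler), their RCDIs are computed, and the eRCDI is the
one-sided normal tolerance limit `mean + k·sd` for a user-chosen
confidence and coverage. A gene whose RCDI exceeds the eRCDI is
deoptimized beyond what its composition alone explains. The package also
reports a Kolmogorov–Smirnov normality check (Lilliefors-corrected) of the
random RCDI distribution — the tolerance limit assumes normality — and
chi-square homogeneity tests of the query set.

## Worked example

```r
library(codonDeopt)
code <- geneticCode(1)                      # standard genetic code

## human-like reference: Ser family gives TCG frequency 567/10000 = 0.0567
vals <- setNames(rep(100, 64), names(code))
ser  <- names(code)[code == "S"]
vals["TCG"] <- 567; vals[setdiff(ser, "TCG")] <- (10000 - 567) / 5
reference <- synonymousFrequencies(codonUsageTable(vals, scale = "counts"), code)

rcdiValue(rcdi(strrep("TCG", 100), reference))
#> [1] 17.63668        # the maximal-deoptimization landmark, 1/0.0567

## three synthetic 120-codon genes
set.seed(42)
pool  <- c("GCC","GCA","TTA","CTG","TCC","TCG","AAA","GAG","GGC","TAT","CAC","GTG","ATG")
genes <- setNames(sapply(1:3, function(i)
           paste(sample(pool, 120, TRUE), collapse = "")), c("vp1","vp2","vp3"))
rcdiTable(computeRcdi(genes, reference), contributions = FALSE)
#>   gene_id n_codons     rcdi gc_percent gc3_percent
#> 1     vp1      120 2.953942   56.94444    70.00000
#> 2     vp2      120 3.131259   59.44444    73.33333
#> 3     vp3      120 3.590198   56.11111    73.33333

expectedRcdi(genes, reference, nRandom = 500, seed = 42)
#> ErcdiResult from 500 random sequences ( poisson )
#>   random RCDI: mean 1.4359, sd 0.1502
#>   eRCDI = 1.8077 (k = 2.4760, confidence 0.95, coverage 0.99)
#>   KS normality: D = 0.0892, Lilliefors p = 3.284e-10
```

All three genes sit far above the eRCDI of 1.81: their codon usage is
deoptimized beyond what their G+C and amino-acid composition explain. The
low KS p-value warns that at this gene length the random-RCDI distribution
is right-skewed (RCDI is bounded below by 1), so the normal tolerance
limit is an approximation — exactly the diagnostic the KS output is for.

Reports with the four output blocks (per-gene parameters with the
per-codon `(CiFa/CiFh)·Ni` terms, global composition, statistical tests,
expected RCDI) are produced by `writeReport(..., format = "tsv"|"json")`,
and `codonIndices()` adds CAI, ENC and expected-ENC columns.

A command-line front end with subcommands `rcdi`, `ercdi`, `indices` and
`random` is installed at `inst/cli/rcdi.R`:

```sh
Rscript inst/cli/rcdi.R ercdi --fasta genes.fasta --codon-table usage.tsv \
    --n-random 500 --seed 42 --with-cai --with-enc --out report.tsv
```

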