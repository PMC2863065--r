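# isoformlm

Linear-model estimation of splice-isoform abundances from RNA-Seq read
counts, with explicit modeling of non-uniform read start-position and
read-length distributions.

## The problem

A gene with *n* known splice isoforms T₁…Tₙ produces reads that often map
to several isoforms at once, so per-isoform read counting breaks down.
Every read can, however, be placed unambiguously into one of at most
2ⁿ − 1 **compatibility subsets** — the set of isoforms whose sequence
contains the read. For a two-isoform cassette-exon gene the subsets are
{T₁} (reads touching the cassette exon), {T₂} (reads spanning the skip
junction) and {T₁, T₂} (reads inside shared exons).

Writing Yᵢ for the number of reads in subset Sᵢ and R for the gene's total,
each Yᵢ ~ Binomial(R, πᵢ) with

    πᵢ = Σⱼ p_ij βⱼ ,   p_ij = Pr(Sᵢ | Tⱼ) ,   βⱼ = Pr(read from Tⱼ)

i.e. **Y = R P β** in matrix form. The design matrix P is computed from the
transcript sequences together with the joint distribution h(k, m | L) of
read start k and length m on a transcript of length L — which in real
libraries is far from uniform and protocol-dependent. β is estimated by
feasible weighted least squares (normal approximation to the binomial,
variances re-estimated from the previous iterate), truncated onto [0, 1]
and renormalized; molar isoform proportions follow from the
length-proportional sampling identity

    Φⱼ = (βⱼ / Lⱼ) / Σₖ (βₖ / Lₖ) ,

with empirical confidence intervals by parametric bootstrap.

Around this core the package provides: kernel-density estimation of
h(k, m | L) from observed alignments (TSV/SAM/BAM); a nebulization
fragmentation simulator; a read simulator for replicated recovery and
coverage studies; multiread handling by k-mer-indexed design-matrix
masking; chi-square tests for differential splicing and two-proportion
z-tests for differential gene expression with Benjamini–Hochberg control;
and a k-mer-sharing gene graph whose connected components define
joint-estimation groups. Synthetic fixture generators make everything
testable without downloads.

## Worked example

```r
library(isoformlm)

g <- make_gene(fixture_spec("cassette_exon", exons = c(7, 10, 10),
                            letters = c("A", "U", "C")))
g
#> gene G1: 2 isoform(s)
#>   G1.1 (27 nt)
#>   G1.2 (17 nt)

dm <- build_design_matrix(g, uniform_model(5L))
dm
#> design matrix for gene G1: 3 subset(s) x 2 isoform(s)
#>             G1.1   G1.2
#> G1.1      0.6087 0.0000
#> G1.2      0.0000 0.3077
#> G1.1+G1.2 0.3913 0.6923
```

Of T₁'s 23 possible length-5 reads, 14 touch the cassette exon (14/23 ≈
0.609, subset {T₁}) and 9 lie in shared sequence; columns sum to 1, the
cross-isoform singleton entries are structurally zero, and the matrix has
rank 2, so both β's are estimable.

```r
y <- simulate_reads(g, phi = c(0.7, 0.3), R = 2000,
                    model = uniform_model(5L), seed = 11)
y
#> subset counts (R = 2000):
#>      G1.1      G1.2 G1.1+G1.2
#>       973       136       891

quantify_gene(g, uniform_model(5L), y, B = 200, seed = 11)
#> isoform estimate for gene G1 (R = 2000 reads)
#>  gene_id transcript_id   phi ci_low ci_high   beta    R truncated
#>       G1          G1.1 0.706 0.6621  0.7461 0.7922 2000     FALSE
#>       G1          G1.2 0.294 0.2539  0.3379 0.2078 2000     FALSE
```

The 70/30 molar mixture is recovered (Φ̂₁ = 0.706, 95% CI 0.66–0.75).
Note β₁ = 0.79 > Φ₁ = 0.71: the longer isoform absorbs proportionally
more reads, which is exactly what the length-deweighting step corrects.

A command-line front end ships in `exec/isoformlm` with subcommands
`fit-readmodel`, `quantify`, `simulate`, `study`, `diff-splice`,
`diff-expr`, `components` and `make-fixtures`; run it without arguments
for usage.

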