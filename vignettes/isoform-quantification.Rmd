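---
title: "Isoform quantification from read compatibility classes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform quantification from read compatibility classes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoformlm)
```

## The model

Given a gene with $n$ known isoforms $T_1,\dots,T_n$ of lengths
$L_1,\dots,L_n$, every read that maps to the gene is compatible with a
non-empty subset of isoforms: the isoforms whose transcript sequence
contains the read as an exact contiguous substring. The compatibility
subsets $S_i$ partition all realizable reads, and with $Y_i$ the count of
reads in $S_i$ and $R$ the gene total,

$$Y_i \sim \mathrm{Binomial}(R,\ \pi_i),\qquad
  \pi_i = \sum_j \Pr(S_i \mid T_j)\,\beta_j = \sum_j p_{ij}\beta_j,$$

so that $E[Y] = R P \beta$. The two modeling assumptions are (i) reads
are independent and identically distributed, and (ii) an isoform is
sampled with probability proportional to its molar concentration times
its length, $\beta_j = \Phi_j L_j / \sum_k \Phi_k L_k$. Assumption (ii)
is what lets a single linear fit of $\beta$ be converted to the molar
proportions $\Phi$, the quantity of biological interest.

Compatibility is exact substring matching by design: alignment (and
therefore tolerance to sequencing error) happens upstream, and the model
consumes already-mapped reads. Mismatch-tolerant matching is a non-goal.

## The design matrix

$p_{ij}$ depends only on the transcript sequences and on
$h(k, m \mid L)$, the joint distribution of read start $k$ and read
length $m$ on a transcript of length $L$: for each isoform $j$, every
feasible window $(k, m)$ with $k + m - 1 \le L_j$ is classified against
all isoforms and its mass $h(k, m \mid L_j)$ accumulated onto the row of
the resulting subset. Columns then sum to one by construction, and the
enumeration is shared verbatim with the read simulator, so simulated
subset frequencies converge to $P\beta$ cell-for-cell.

$h$ is factorized as an independent product of a start-position density
on the relative coordinate $u = k/L$ and a read-length pmf, renormalized
over the feasible window set of each transcript. The factorization
mirrors how the two distributions are estimated (separately, with start
positions expressed as a fraction of transcript length) and keeps one
pooled positional model across transcript lengths; per-length
stratification would only need a second model object.

Rows grow as $2^n - 1$, but `reduce_to_full_rank()` can restrict to the
$n$ singleton rows (always full rank when isoforms are distinguishable)
or pool rows of negligible mass (`merge_small`, default threshold
$10^{-4}$ row mass). Rank is verified numerically on singular values at
tolerance $10^{-10}$; duplicate-sequence isoforms are reported as
indistinguishable groups rather than silently producing garbage.

## Estimating the read model

`estimate_read_model()` uses a Gaussian kernel density estimate of the
relative start positions with Silverman's rule-of-thumb bandwidth,
boundary reflection at 0 and 1, and evaluation on a 512-point grid; the
read-length pmf is the empirical distribution. The bandwidth is
configurable because no single choice suits both a sharply 5'-skewed
library and a nearly flat one; reflection prevents the familiar halving
of mass at the support edges. A floor of 100 alignments guards against
fitting a density to noise. One systematic feature is worth knowing:
reads cannot start within the last $m - 1$ bases of a transcript, so the
estimated density dips near $u = 1$; the feasible-region renormalization
in `discretize()` makes this harmless downstream.

`simulate_nebulization()` emulates gas-shear cDNA fragmentation: each
molecule is recursively cut at a uniform random point until no piece
exceeds `frag_max`; pieces inside `[frag_min, frag_max]` (defaults
500–800 nt) survive size selection, and a read start is recorded at each
retained fragment's 5' end. Reads are taken from the 5' end only by
default — the single-end protocol — with a `both_ends` flag for
two-end sequencing, a detail the fragmentation physics itself does not
fix. The resulting start density on, say, 1200-nt molecules is strongly
non-uniform (enriched toward the 5' terminus), and is the skewed
generator used in the package's studies. Sequence-specific effects (GC
content, terminal ditags) are outside the model.

## Estimation

With the normal approximation to the binomial, weighted least squares
with weights $1/\mathrm{Var}(Y_i)$ is the best linear unbiased
estimator; the variances are unknown, so *feasible* WLS re-estimates
them from the current fit: ordinary least squares start, then by default
two reweighting passes with $\widehat{\mathrm{Var}}(Y_i) = R
\hat\pi_i(1 - \hat\pi_i)$ (a `tol` argument switches to iteration to
convergence, capped at 50 passes; in practice the second pass already
moves estimates by less than the Monte-Carlo noise). A variance floor of
$\max(R\hat\pi(1-\hat\pi),\ 0.25)$ keeps weights finite when a fitted
$\hat\pi_i$ touches 0 or 1. The covariance is treated as diagonal, per
the marginal binomial model; multinomial cross-covariances are ignored.

Out-of-range coefficients are truncated to $[0,1]$ first and the vector
renormalized to sum to one second, so the output is always a simplex
point (the reverse order is not). The same renormalization absorbs the
global scale factor that a multiread-masked fit carries: with retained
column masses $c_j < 1$, the linear fit returns coefficients
proportional to $\beta_j / \sum_k c_k \beta_k$, and dividing by their
sum recovers $\beta$ exactly — the noise-free masked case is covered by
a unit test. Estimation refuses genes with fewer than 20 reads (the
normal-approximation guard, configurable).

Confidence intervals are parametric-bootstrap percentile intervals:
$B = 200$ multinomial resamples of size $R$ from the fitted
$\hat\pi$, each re-estimated and converted to $\Phi$. The package's
replicated studies show empirical coverage within Monte-Carlo error of
nominal at 65/90/95% for $R = 2000$; percentile intervals at $B = 200$
can run one to two points below nominal at the 95% level, which is the
accuracy bound to keep in mind.

## The simulation studies

`run_simulation_study()` repeats, per replicate: simulate subset counts
at the true mixture under a *generator* model, estimate with a design
matrix built from an *estimation* model, record $\hat\Phi$ and interval
hits. The package's standard study — also what `scripts/acceptance.R`
runs — uses a synthetic two-isoform cassette-exon gene (exons
500/150/550 nt, so 1200 and 1050 nt isoforms, matching a typical
transcript length), a 70/30 mixture, 500 replicates of 2000 reads,
30-nt reads under the nebulization model, and $B = 200$ bootstrap
replicates. These sizes keep a full study around half a minute on one
core while leaving the Monte-Carlo standard error of the mean estimate
near $1.5\times10^{-3}$, small enough to detect biases of half a
percentage point. Replicate seeds derive deterministically from the
study seed (seed + replicate index), so studies are bit-reproducible.

When generator and estimation model match, the mean estimate is
unbiased to within Monte-Carlo error. When they do not — reads skewed,
estimation assuming uniformity — the major-isoform estimate on this
fixture is biased upward by tens of percentage points: using the wrong
positional distribution does not merely widen intervals, it moves the
answer, and can reorder isoform abundances. That contrast is asserted
as a property (mismatched bias strictly exceeds matched bias) rather
than as a fixed number, because its magnitude is specific to the gene
geometry and the skew.

What the generator does *not* emulate: sequencing errors and quality
scores (reads are exact substrings), sequence-specific sampling biases,
paired ends, and annotation errors (the annotated isoform set is taken
as ground truth — residual diagnostics for hidden isoforms are future
work). Passing tests therefore demonstrate correctness of the
estimator under its own model, not robustness to misannotation.

## Differential tests

Differential splicing between two conditions is a Pearson chi-square
test on the subsets × conditions count table, dropping subsets empty in
both conditions (df = kept subsets − 1), with no continuity correction;
a warning flags expected cells below 5. Genes are tested only if, with
both conditions pooled, at least two isoforms have a read in their
unique (singleton-subset) regions — without such reads the table is
uninformative about splicing. Untestable genes are skipped, not errored.
The "main isoform" of a comparison is defined in the first condition
(largest $\Phi$, ties to the lowest index); a symmetric
max-over-isoforms variant sits behind a flag since the anchoring choice
is a convention.

Differential gene expression uses the pooled two-proportion $z$ test on
per-sample read fractions; with sample totals in the tens of millions
the standard normal reference is accurate. Both test families are
corrected by Benjamini–Hochberg step-up, default FDR 0.01; the FDR level
is the exposed parameter, and any p-value cutoff it induces is
data-dependent, not a constant of the method.

## Multireads and the gene graph

Reads mapping to multiple genes are handled by discarding them *after*
adjusting the design matrix: every candidate window is checked against
all other genes (k-mer index prefilter, default $k = 25$, then exact
substring confirmation) and shared windows contribute no mass. Windows
shorter than $k$ fall back to a direct scan, so the screen never misses
a sharing that the exact test would find. The alternative — joint
estimation of all genes sharing sequence — is delimited by
`connected_components()` on the graph joining genes that share a
25-mer; component sizes tell you when joint estimation is tractable and
when (gene families of 50+ members) it is not. K-mers are indexed on
the given strand only, since transcript orientation is known, with a
`both_strands` option; low-complexity k-mers are *not* filtered by
default — they genuinely create large components — but an entropy
filter is available to study that effect.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive; a read of length $m$ at start $k$
  requires $k + m - 1 \le L$.
* U and T are canonicalized to one letter at load time; any other
  character is a hard error naming the offending record.
* Subset order is canonical (cardinality, then indices) so matrices,
  counts and reports are byte-reproducible.
* `discretize()` renormalizes to sum exactly 1 and errors when a
  transcript is shorter than every modeled read length.
* Identical-sequence isoforms yield a single shared subset and are
  reported as indistinguishable at rank reduction.
* A fit whose truncated coefficients sum to zero (all counts in
  impossible rows) falls back to the uniform simplex point and is
  flagged.
* All stochastic entry points take an explicit integer seed.

## Limitations

The estimator inherits the model's assumptions: known and complete
isoform annotation, iid reads, length-proportional sampling, and a
positional distribution that is a property of the protocol rather than
of the individual transcript. Genes whose isoforms are not
distinguishable at the modeled read lengths are reported as errors, not
guessed at. The chi-square splicing test compares subset-count
composition, which is sensitive to any compositional shift — including
ones too small to be biologically interesting; the main-isoform
difference is reported alongside exactly so effect size can be judged
separately from significance.
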