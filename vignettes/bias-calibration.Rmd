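---
title: "Estimating, partitioning and explaining metabarcoding bias with mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating, partitioning and explaining metabarcoding bias with mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mockbias)
```

## The problem

Metabarcoding read counts are compositional: only the proportions of reads
among taxa carry information, and even those proportions are distorted.
Species-specific traits interact with each laboratory step — a hard,
sclerotized exoskeleton impedes non-destructive lysis; primer-template
mismatch suppresses amplification; amplicon base composition affects both
PCR and sequencing — so every taxon is recovered with its own multiplicative
detection efficiency. `mockbias` measures those efficiencies with mock
communities (pools of counted individuals, pooled genomic DNA, and pooled
amplicons), partitions them by workflow stage, and models them from traits.

## Model and estimator

For a sample from pool $p$ with known composition $x_p$ (restricted to the
taxa actually present, then closed to sum to one), the observed composition
is modelled as proportional to $x_p \cdot b$ with $b$ a positive efficiency
vector. Because any constant cancels under closure, $b$ is identified only
up to scale; we geometrically center it ($\mathrm{gm}(b) = 1$), making each
entry an enrichment or depletion relative to the average taxon.

The per-sample *compositional error* is
$\mathrm{center}(\mathrm{observed} / \mathrm{expected})$, and the estimator
for a group of samples is the per-taxon geometric mean of those errors over
the samples in which the taxon was both expected and observed, re-centered.
On the log scale this is the ordinary-least-squares solution of a linear
model of the compositional error with one indicator per taxon, which is why
the noiseless-recovery tests can demand exactness to numerical precision.

Assumptions worth stating: bias acts multiplicatively and identically on
every sample of a group; samples are independent replicates; taxa absent
from a pool contribute nothing (they are removed and both vectors
re-closed). Observed zeros for expected taxa are handled by a **zero
policy**: the default excludes the cell from that sample's error vector and
records it as a dropout (a ratio with zero has no logarithm, and imputing
can masquerade a qualitative failure, such as template degradation, as a
quantitative one); an optional pseudocount (default 0.5 reads, added before
closure) retains all taxa and is appropriate when zeros reflect shallow
sequencing rather than failed recovery.

Uncertainty comes from resampling samples (not taxa) with replacement
within the group — 1000 replicates by default — summarised as log-scale
standard errors and percentile intervals (95% and 50%, the two intervals
conventionally displayed). With few samples per group the percentile
bootstrap is known to undercover slightly; the package's own simulations
(see the test suite) put coverage near 88% at 8 samples and 92% at 24
samples for a nominal 95% interval. Interval widths should be read with
that in mind.

## Partitioning by workflow stage

Three kinds of mock pools enter the workflow at different points: whole
insects (all three stages), pooled DNA extracted destructively per species
(PCR + sequencing), and pooled per-species amplicons (sequencing +
bioinformatics only). Under the multiplicative model,

$$
b_{\mathrm{extraction}} = \mathrm{center}(b_{\mathrm{insect}} / b_{\mathrm{dna}}),\quad
b_{\mathrm{pcr}} = \mathrm{center}(b_{\mathrm{dna}} / b_{\mathrm{amplicon}}),\quad
b_{\mathrm{sequencing}} = \mathrm{center}(b_{\mathrm{amplicon}}),
$$

and the re-centered product of the three reconstructs the centered total
bias exactly — a telescoping identity the acceptance tests check to 1e-9.
Whether one re-centers each component or only once is immaterial to that
reconstruction; we re-center each component so that every reported vector
is interpretable on its own. The DNA and amplicon pools were built by
destructive extraction and are therefore shared between the two
non-destructive extraction protocols: extraction components differ per
protocol, PCR/sequencing components only per primer set.

Component uncertainty is propagated by combining replicate $r$ of each
stage's bootstrap (valid because the three stage groups are disjoint sample
sets, so this is a joint bootstrap); when replicate matrices are unavailable
or of unequal size the package falls back to adding log-scale variances and
says so in the object.

Per-step **trajectories** multiply a starting abundance of one by each
component in workflow order, re-centering after every step; the final step
equals the centered total bias.

## Trait regression

Log efficiency is regressed by OLS on: exoskeleton-hardness indicators
(1 = soft, 2 = intermediate, 3 = hard), log body volume (volumes in the
packaged table span 0.17–26.51 mm³, and effects are multiplicative, so the
log scale is the natural default; a raw-volume switch exists), combined
primer mismatch (forward + reverse proportions — the two primers' mismatches
are additive in their effect on the log scale, and no published combination
rule exists, so the simplest was chosen), and amplicon GC fraction.

Two hardness encodings are provided because the reporting convention is
genuinely ambiguous: the default carries all three level indicators with no
intercept (each hardness coefficient is that level's own baseline, matching
how all three levels are usually displayed); the alternative uses an
intercept with hard as the reference level, which yields the familiar
$F(5, n-6)$ summary. Neither is asserted to be "the" canonical encoding;
they give identical fitted values.

Coefficients are reported on the log scale and exponentiated. Confidence
intervals come from refitting the regression to each bootstrap replicate of
the bias estimate and taking percentile bounds on the exponentiated scale;
replicates in which a taxon is missing (it can vanish from a bootstrap
resample when it is expected in few pools) are refit on the rows available
in that replicate. Responses can be stacked over primer sets and sequencing
runs — e.g. 16 taxa x 2 primers x 2 runs = 64 observations — with the
design matrix rows repeated per block.

`mismatch_proportion()` regenerates the mismatch trait from sequences:
the fraction of primer positions whose IUPAC degeneracy set excludes the
template base, rounded to two decimals to match the packaged table.
`amplicon_length()` uses the end-minus-start coordinate convention that
reproduces the conventional printed amplicon lengths (346–551 → 205 bp;
346–560 → 214 bp).

## Richness comparisons

Presence/absence sensitivity is compared between treatments after rarefying
every sample to a common depth (default 100,000 reads) by multivariate
hypergeometric subsampling without replacement (via `vegan::rrarefy`), one
seeded draw per sample; samples below the target depth are dropped rather
than retained, which is the conservative convention (a negative control
with a few hundred reads cannot meaningfully be rarefied to 100,000).
Group differences in per-sample richness are tested with a one-way ANOVA
and Tukey's HSD. The printed degrees of freedom of such analyses imply
one-way comparisons on sample subsets rather than a crossed factorial
model, and that is what the package implements. The all-values-identical
degenerate case reports F = 0 with a warning rather than 0/0.

## The synthetic-data generator

`sim_params()` defines a complete experiment emulating the three-pool
design: eight mock pools (packaged design table; two extraction protocols
over pools 1–4 and 5–8), two primer sets, replicate sequencing runs, and the
three entry stages with shared DNA/amplicon pools. Per-step true log bias is
a trait design-matrix product plus lognormal taxon noise (sd 0.2 per step by
default), centered; extraction truth depends on morphological traits only.
Counts are multinomial at a normally distributed depth — defaults mirror a
MiSeq mock-community run at mean 272,600 reads (sd 3,762) per sample — with
optional symmetric-Dirichlet overdispersion and per-cell dropout zeroing
(mimicking, qualitatively, the template-degradation dropouts seen in stored
extracts). Default effect directions follow the biology described above:
soft-bodied taxa extract better, mismatch suppresses and GC aids PCR.

The generator is a pure function of its parameter object: truth is drawn
from the master seed, and sample $j$ draws its counts from an independent
substream seeded at `seed + 1 + j`, which makes the stage structure testable
— changing the bias entering one stage leaves the draws of samples that
skip that stage bit-identical.

What the simulation deliberately does *not* emulate: sequence-level effects
(chimeras, denoising artefacts, classification error), tag-jumping,
cross-contamination, between-run batch effects, or correlated taxon noise.
Passing the recovery tests therefore demonstrates the statistical machinery
is correct under the multiplicative model, not that real data satisfy that
model.

## Numerical choices and degenerate inputs

- Closure and centering tolerances are 1e-9; centering is idempotent and
  zeros are rejected (callers apply the zero policy first).
- All-zero observed vectors, empty groups, unknown pools, mismatched taxon
  sets and rank-deficient trait designs raise immediate, named errors.
- Groups of one sample or single bootstrap replicates yield zero standard
  errors with a warning rather than NA.
- RMSE between observed and expected compositions is reported in percentage
  points and, by default, pools all sample-taxon cells of a group into one
  root mean square (one number per group/panel); a per-sample-then-average
  mode is exposed because published practice is ambiguous between the two.
- Every stochastic function takes an explicit integer seed; pipeline
  bootstrap seeds are derived from the run seed in a fixed call order, so
  rerunning a configuration is byte-identical.

## Problem sizes used in validation

The test suite and acceptance script validate at reduced scale chosen to
keep the full run in tens of seconds while leaving the statistics
well-resolved: simulated depth 20,000 reads (sd 500) for recovery studies,
500 bootstrap replicates for the end-to-end check, 100–200 simulated
datasets for coverage studies, and 1e6–1e7 notional reads for
noiseless/law-of-large-numbers checks. The estimator and partition
identities are scale-free, so exactness at these sizes is exactness.

## Known limitations

- Taxa expected in very few pools (one species occurs in only two) are
  estimated from few samples; their intervals are honest but wide, and they
  can drop out of bootstrap resamples entirely (handled, but flagged).
- The trait regression treats the bias point estimates as the response;
  estimation error in the response is captured by the replicate-wise refits,
  not by an errors-in-variables model.
- Percentile bootstrap intervals undercover at small group sizes (see
  above); a future BCa option would tighten this.
- The multiplicative model cannot represent qualitative failures (true
  zeros); those surface as dropouts, not as small efficiencies.
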