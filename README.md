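# mockbias

Quantitative calibration of insect DNA metabarcoding with mock communities.

Metabarcoding of bulk insect samples reports *relative* read abundances, and
those abundances are systematically distorted: every taxon is over- or
under-represented by a multiplicative factor — its **detection efficiency** —
introduced during DNA extraction, PCR amplification and
sequencing/bioinformatics. `mockbias` estimates those efficiencies from mock
communities of known composition, splits total protocol bias into its
per-stage components, relates bias to insect traits, and ships a synthetic
three-stage experiment generator with known ground truth so the whole
pipeline is testable end to end.

It is aimed at entomologists and molecular ecologists running
(non-destructive) metabarcoding for surveillance, biosecurity or
biodiversity assessment who want to know *how wrong* their read proportions
are, *where* the distortion enters, and *which taxa* are at risk of dropping
below the detection limit.

## The model

For a sample with expected (known) composition `x` over the taxa present,
the observed composition from sequencing is modelled as

```
observed ∝ x · b,            b = b_extraction · b_pcr · b_sequencing
```

where `b` is a vector of per-taxon multiplicative efficiencies, identifiable
only up to a constant and therefore geometrically centered: `gm(b) = 1`, so
each entry reads as enrichment or depletion relative to the "average" taxon.
Each sample's **compositional error** is the centered ratio
`observed / expected`; the per-taxon efficiency estimate is the geometric
mean of these errors across a group's samples (the closed form of a linear
model of the compositional error), with uncertainty from bootstrap
resampling of samples.

Mock pools entering the workflow at three points identify the stage
components by element-wise division:

- whole-insect pools measure `b_total = b_ext · b_pcr · b_seq`,
- pooled genomic DNA measures `b_pcr · b_seq`,
- pooled amplicons measure `b_seq`,

so `b_ext = center(b_total / b_dna)`, `b_pcr = center(b_dna / b_pcr-pools)`,
`b_seq = center(b_pcr-pools)`, and the re-centered product reconstructs
`b_total` exactly. A log-linear regression then attributes efficiency to
morphological traits (body volume, exoskeleton hardness) and molecular
traits (primer-template mismatch, amplicon GC fraction).

## Worked example

Simulate a full two-protocol, two-primer, two-run experiment at realistic
MiSeq depth, then estimate and partition the bias of the DNeasy-extracted
whole-insect pools:

```r
library(mockbias)

params <- sim_params(seed = 2024)          # packaged 8-pool design + traits
sim <- simulate_experiment(params)

est <- bootstrap_bias(sim$counts, sim$meta, params$design,
                      group = list(stage = "insect", extraction = "dneasy",
                                   primer = "fwhF2-fwhR2n"),
                      n_boot = 1000, seed = 1)
tibble::as_tibble(est)
#> # A tibble: 16 x 8
#>   taxon                 efficiency  se_log ci_lo ci_hi ci50_lo ci50_hi n_dropout
#>   <chr>                      <dbl>   <dbl> <dbl> <dbl>   <dbl>   <dbl>     <int>
#> 1 Carpophilus davidsoni      0.449 0.00293 0.447 0.451   0.448   0.450         0
#> 2 Carpophilus truncatus      0.858 0.00643 0.848 0.869   0.855   0.862         0
#> 3 Bactrocera tryoni          1.24  0.00330 1.23  1.25    1.24    1.24          0
#> 4 Bradysia nr. ocellar…      0.730 0.00799 0.720 0.740   0.725   0.736         0
#> # i 12 more rows
```

`efficiency` is each taxon's detection efficiency relative to the
geometric-mean taxon: here *Carpophilus davidsoni* yields ~0.45x the reads
its abundance warrants, while *Bactrocera tryoni* is enriched ~1.24x.

```r
dna <- bootstrap_bias(sim$counts, sim$meta, params$design,
                      list(stage = "dna", primer = "fwhF2-fwhR2n"),
                      n_boot = 1000, seed = 2)
pcr <- bootstrap_bias(sim$counts, sim$meta, params$design,
                      list(stage = "pcr", primer = "fwhF2-fwhR2n"),
                      n_boot = 1000, seed = 3)
part <- partition_bias(est, dna, pcr, protocol = "dneasy",
                       primer = "fwhF2-fwhR2n")
tibble::as_tibble(part)
#> # A tibble: 48 x 6
#>   taxon                  component  efficiency  se_log ci_lo ci_hi
#>   <chr>                  <chr>           <dbl>   <dbl> <dbl> <dbl>
#> 1 Carpophilus davidsoni  extraction      0.560 0.00668 0.556 0.563
#> 2 Carpophilus truncatus  extraction      0.742 0.00991 0.729 0.753
#> 3 Bactrocera tryoni      extraction      2.14  0.00884 2.11  2.16
#> 4 Bradysia nr. ocellaris extraction      0.506 0.00922 0.497 0.515
#> # i 44 more rows
```

`bias_trajectory(part)` turns the components into per-taxon abundance
trajectories (start = 1, then x extraction, x PCR, x sequencing), and
`plot_bias(est)` / `plot_trajectory(...)` draw them. The trait regression:

```r
X <- build_trait_design(insect_traits_fixture(), names(est$efficiency),
                        "fwhF2-fwhR2n")
fit <- bootstrap_trait_cis(est, X)
fit
#> <trait_model_fit> hardness_levels
#>   n = 16, F(6, 10) = 1.28, adj. R^2 = 0.10, p = 0.346
#> # A tibble: 6 x 5
#>   term         estimate_log estimate  ci_lo   ci_hi
#> 1 soft               -0.289   0.749  0.734   0.769
#> 2 intermediate       -0.597   0.550  0.539   0.565
#> 3 hard               -1.10    0.333  0.325   0.343
#> 4 log_volume          0.118   1.13   1.12    1.13
#> 5 mismatch           -2.65    0.0709 0.0679  0.0745
#> 6 gc                 2.35    10.5    9.62   11.2
```

Exponentiated coefficients are multiplicative effects on detection
efficiency per unit trait: a mismatch coefficient of 0.07 means a taxon
mismatching the whole primer would be recovered at ~7% of the average
taxon's rate. On this single-group fit bias correction cut the RMSE between
observed and expected relative abundances from 3.6% to 0.0% (the printed
output of `rmse_composition()` before and after `predict_composition()`).

`run_pipeline(run_config(...))` chains everything — per-group estimates,
partitions, trajectories, trait models, RMSE report and rarefied-richness
ANOVA/Tukey — and writes deterministic TSV/JSON bundles. A thin subcommand
CLI lives at `inst/scripts/mockbias-cli.R`.

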