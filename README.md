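# proxitome

Analysis toolkit for **hybridization proximity labeling (HyPro)**
experiments, in which a peroxidase tethered to an RNA-FISH probe deposits
biotin on proteins near a chosen RNA compartment (a perinucleolar
compartment, a transcription site, a single repeat-expanded transcript),
and the biotinylated proteome is read out by label-free quantitative
(LFQ) mass spectrometry while the labeled compartments themselves are
quantified by single-molecule RNA FISH microscopy.

The package implements the full desk-side analysis stack for such
experiments, together with a synthetic-data generator that produces every
input type with known ground truth, so each stage can be validated for
recovery of planted signal.

## What it computes

**Differential enrichment and shortlisting** (`crapome_filter`,
`replicate_presence_filter`, `impute_minprob`, `fit_moderation`,
`moderated_t`, `pvalue_z`, `shortlist`, `filter_nuclear`): candidate
compartment proteins from protein-by-sample log2 LFQ intensities.
Contaminants are removed when present in > 50% of control experiments
with > 15 mean spectral counts (keratins always); proteins must be
identified in all replicates of at least one condition; remaining missing
values are imputed from a left-shifted Gaussian at the per-sample 1%
quantile (MinProb). Per-protein variances s² with d residual degrees of
freedom are shrunk toward an empirical-Bayes prior (d₀, s₀²) estimated by
moment-matching log variances, giving the moderated t statistic

    t = (mean_A − mean_B) / sqrt(s²_post (1/n_A + 1/n_B)),
    s²_post = (d₀ s₀² + d s²) / (d₀ + d),   df = d₀ + d.

A protein is shortlisted when fold change ≥ 1.5, unadjusted two-sided
p < 0.05, and the p-value-based Z-score Z = Φ⁻¹(1 − p/2)·sign(log2FC)
exceeds 1 — optionally also exceeding the protein's Z in a competing
compartment or cell line — and carries nuclear annotation.

**Interaction enrichment** (`count_edges`, `sample_null`,
`enrichment_test`, `build_combined_network`): the number of scored
protein–protein interaction edges (score > 0.4 / 0.7 / 0.9) inside a
shortlist is compared against *simulated proteomes* — 100 equal-sized
sets sampled at random from the mass-spec-detectable background — with
fold enrichment over the simulated median and a two-sided one-sample
Wilcoxon signed-rank p-value (exact by enumeration for n ≤ 12, otherwise
a tie-corrected normal approximation).

**Annotation overlap** (`fisher_overlap`, `venn_overlap`): two-sided
Fisher's exact tests (minimum-likelihood rule, conditional-MLE odds
ratio) against an explicit background universe.

**Image quantification** (`detect_spots`, `calibrate_unit_intensity`,
`decompose_focus`, `cluster_foci`, `colocalize`, `labeling_efficiency`,
`line_profile_decay`, `intensity_near_focus`, `periphery_partition`):
spot detection at the PSF scale, molecule counting of dense foci against
isolated single-molecule intensity standards, dual-color
mutual-nearest-neighbor colocalization, fraction of biotin-labeled FISH
foci, exponential decay-rate fitting I(x) = A·e^(−kx) + c of label halos
(larger k = less diffusion), near-focus immunofluorescence quantification
with rank-sum comparison, and equal-area center/periphery partitioning of
nuclear masks with a Fisher test of focus distributions.

**Synthetic data** (`generate_lfq_dataset`, `generate_ppi_network`,
`generate_image_stack`, `generate_annotation_table`): triplicate LFQ
intensities with spike-in enrichment, heterogeneous variance and
intensity-dependent (logistic MNAR) dropout plus a CRAPome-like control
count table; community-structured scored interaction networks;
diffraction-limited 3-D stacks with known per-focus molecule counts and
exponential label halos.

## Worked example

A complete synthetic run — generate, filter, impute, test, shortlist,
and measure interaction enrichment:

```r
library(proxitome)
cfg <- run_config(seed = 1,
  lfq_sim = list(n_background = 1000, n_spiked_per_condition = 30,
                 effect_log2fc = 2),
  net_sim = list(n_modules = 5, p_within = 0.15, p_between = 0.02),
  n_samples = 100)
report <- run_pipeline(cfg)
#> simulate: 1030 proteins, 24278 network edges
#> lfq: 31 shortlisted proteins (d0 = 12.52)
#> ppi: set of 31 vs background 942
str(report$stages$ppi$enrichment$cutoff_0.7)
#> List of 5
#>  $ cutoff     : num 0.7
#>  $ observed   : int 57
#>  $ null_median: num 11
#>  $ fold       : num 5.18
#>  $ p          : num 3.38e-18
```

Reading the numbers: of 1030 simulated proteins, the contaminant and
replicate filters leave 942; the moderated t against the no-probe control
(estimated prior d₀ ≈ 12.5) shortlists 31, recovering the 30 truly
spiked proteins. Because the spiked proteins were planted inside one
interaction module, the shortlist contains 57 high-confidence edges where
random same-size proteomes have a median of 11 — a 5.2-fold enrichment
with signed-rank P ≈ 3×10⁻¹⁸, the resolution limit of 100 simulated
proteomes. The report also records survivor counts per filter
(`report$stages$lfq$filters`) and the configuration hash that produced
it.

A thin command-line wrapper over the same functions is installed at
`inst/cli/proxitome.R` with subcommands
`simulate | lfq | ppi | enrich | image | run`.

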