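---
title: "Methods: models, parameters and design choices in proxitome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in proxitome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitome)
```

proxitome analyzes hybridization proximity labeling experiments: an
RNA-FISH probe carries a peroxidase to a chosen RNA compartment, the
enzyme biotinylates proteins within a short labeling radius, and the
experiment is read out twice — by label-free quantitative (LFQ) mass
spectrometry of the biotinylated proteome, and by multi-channel
single-molecule FISH microscopy of the labeled compartments. This
vignette documents the statistical models, the tunable parameters, and
the design decisions behind each stage, including what the synthetic
data generator does and does not emulate.

## Differential enrichment of LFQ proteomes

### Model

Protein intensities are analyzed on the log2 scale. After contaminant
and replicate filtering and imputation (below), each protein has a
complete `conditions x replicates` block. The two-group comparison of a
probe condition A against the no-probe control B uses an
empirical-Bayes moderated t statistic: the pooled within-group variance
$s^2$ with $d$ residual degrees of freedom is shrunk toward a prior
$(d_0, s_0^2)$,

$$ s^2_{\mathrm{post}} = \frac{d_0 s_0^2 + d s^2}{d_0 + d}, \qquad
   t = \frac{\bar{x}_A - \bar{x}_B}
            {s_{\mathrm{post}}\sqrt{1/n_A + 1/n_B}}, $$

with two-sided p-values on $d_0 + d$ degrees of freedom. The prior is
estimated by moment-matching the distribution of log variances: under
the scaled-F model, $\log s^2$ has mean
$\log s_0^2 + \psi(d/2) - \log(d/2)$ (up to the analogous $d_0$ terms)
and excess variance $\psi'(d_0/2)$, so $d_0$ is obtained by inverting
the trigamma function (Newton iteration, relative tolerance $10^{-10}$)
and $s_0^2$ from the corrected mean. When the observed log-variance
dispersion does not exceed what the residual degrees of freedom alone
explain, $d_0$ is reported infinite and $s_0^2$ is the mean variance;
all-zero variances are flagged degenerate. With $d_0 = 0$ the statistic
reduces exactly to the ordinary pooled two-sample t (a unit-tested
identity, tolerance $10^{-10}$; the implementation is also cross-checked
against limma on shared hyperparameters).

P-values are deliberately **not** adjusted for multiple testing: the
shortlisting convention works on unadjusted p-values, and the final
candidate list is controlled by the joint fold-change/p/Z rule rather
than by FDR.

### Shortlisting rule and thresholds

A protein is shortlisted when all of the following hold against the
no-probe control (defaults in parentheses):

* fold change $2^{\log_2 FC} \ge$ `fc_thr` (1.5), **inclusive**;
* two-sided $p <$ `p_thr` (0.05), **strict**;
* p-value-based Z-score $Z >$ `z_thr` (1), **strict**;
* when a competing comparison is supplied (a second compartment or a
  control cell line), $Z$ must strictly exceed the same protein's
  competitor $Z$; proteins absent from the competitor table pass
  (treated as $Z = -\infty$).

The *p-value-based Z-score* is interpreted as the signed normal
quantile of the unadjusted two-sided p-value,
$Z = \Phi^{-1}(1 - p/2)\,\mathrm{sign}(\log_2 FC)$. Under this reading
$Z > 1$ is implied by $p < 0.05$ for positive fold changes, making the
thresholds partially redundant; the redundancy is accepted because the
quantile reading is the only one that makes the cross-compartment
comparison of Z-scores well defined on a common scale. An alternative
reading (distribution-standardized $-\log_{10} p$) was considered and
rejected because it makes Z depend on the ambient protein set. Zero
p-values are clipped to the smallest positive double, with a message.

The contaminant filter removes keratins and proteins present in
strictly more than `freq_thr` (0.5) of control experiments with mean
spectral count over the protein-positive controls strictly greater than
`count_thr` (15). Both inequalities are strict, so presence exactly 50%
or mean count exactly 15 is retained. Proteins absent from the control
compendium are retained and logged, never silently dropped. The
replicate filter keeps a protein when at least one condition has no
missing replicate. Nuclear filtering accepts evidence in either the
"main" or "additional" localization columns; unannotated proteins are
dropped with a warning. Duplicate protein identifiers are an input
error, not silently merged.

### Normalization and imputation

No normalization method is prescribed by the shortlisting procedure
itself; the package defaults to per-sample median centering on the log2
scale (switchable off), because sample-loading offsets otherwise
dominate the synthetic two-group comparisons. Missing values are imputed
MinProb-style: draws from a Gaussian centred at the per-sample
`q`-quantile (`q` = 0.01) of observed values. The spread is `sd_scale`
(1.0) times the **median protein-wise SD** of observed values — the
convention of the reference MinProb implementation — rather than the
per-sample SD of all observed intensities; the latter mixes
between-protein spread (~2 log2 units) into what should be a
measurement-noise scale and would routinely impute values above the
sample median, defeating the left-censoring model. Observed cells are
never altered, and imputation is deterministic given its seed.

## Interaction enrichment against simulated proteomes

The observed count of unique interaction edges inside a protein set
(score **strictly** greater than the cutoff; 0.4 / 0.7 / 0.9 are the
conventional confidence tiers) is compared with a null distribution of
counts from `n_samples` (100) *simulated proteomes*: sets of the same
size sampled from the mass-spec-detectable background. Sampling is
**without replacement within each draw** — a proteome cannot contain
the same protein twice — and independent across draws. Fold enrichment
is observed over the **null median** (not the mean), and the p-value is
a two-sided one-sample Wilcoxon signed-rank test of the null counts
against the observed value: zero differences are dropped, absolute
differences receive average ranks, and

* for $n \le 12$ non-zero differences the p-value is exact, enumerating
  all $2^n$ sign assignments (unit-tested against an independent
  enumeration at tolerance $10^{-12}$);
* otherwise a tie-corrected normal approximation **without continuity
  correction** is used. With all 100 null counts on one side of the
  observed value this saturates at $p \approx 3.9 \times 10^{-18}$,
  which is the resolution limit of the design, not a measure of effect
  size; the fold carries the effect size.

A null median of zero leaves the fold undefined and flagged rather than
infinite. Unscored interaction sources (supported-pair resources
without confidence scores) are included on request, bypassing the
cutoff. The combined two-source network view keeps one node pair with
one tagged link per supporting source, drops isolated proteins, and
defines node degree as the number of distinct partners.

## Fisher overlap statistics

Two-sided Fisher p-values sum hypergeometric point probabilities no
larger than the observed table's probability (minimum-likelihood rule,
with the customary $1 + 10^{-7}$ relative tie tolerance); the odds ratio
is the conditional MLE under the noncentral hypergeometric model,
solved by root-finding on $E_\psi[a]$, reported as 0 or $\infty$ on the
support boundary and undefined for degenerate margins. The background
universe is a **required argument**: compartment enrichments must be
tested against the mass-spec-detectable (and, where applicable,
nuclear) pool, and inferring the universe silently from the annotation
table is the classic way to inflate enrichment.

## Image quantification

### Conventions

Voxel indices are 0-based; a voxel with index $i$ spans $[i, i+1)$ in
voxel units, so its center is at $i + 0.5$ and physical positions are
voxel coordinates times the voxel size. Default geometry is 0.22 µm
optical sections and 0.065 µm camera pixels (100x objective); all radii,
lengths and decay rates are in micrometres. Cluster radii are physical
(µm), not voxel units, so anisotropic sampling cannot distort grouping.

### Spot detection and molecule counting

Detection runs a difference-of-Gaussians band-pass at the PSF scale
(default $\sigma = (1.2, 1.5, 1.5)$ voxels), takes strict 26-neighbor
local maxima above a threshold expressed as a fraction (default 0.1) of
the maximum response — so globally rescaling an image does not move
detections — and refines positions by background-subtracted
intensity-weighted centroids. Integrated intensities are sums over a
$\pm 3\sigma$ window after subtracting the median of the window shell.
A spot is *isolated* when no other detection lies within $2\sigma$
along every axis; isolated spots are the single-molecule intensity
standards, and their median integrated intensity is the reference for
dense-focus decomposition (at least 10 by default). Decomposition is
round-to-nearest of the intensity ratio with a floor of one molecule —
a declared simplification of Gaussian-mixture refinement that is
identical on well-separated synthetic data. The median standard is
meaningful only when single molecules dominate the detected population,
as they do in real acquisitions where cytoplasmic mRNAs far outnumber
transcription sites.

Molecules are grouped into foci by single-linkage clustering within a
physical radius (chains merge), and a focus is a "cluster" when its
total molecule count reaches `min_spots` (2), so "single" is equivalent
to count 1. Dual-color matching is mutual-nearest-neighbor under a
distance cap, which makes the matching one-to-one without a greedy
tie-break.

### Decay profiles and spatial statistics

Line profiles are sampled with trilinear interpolation at half-pixel
steps, max-normalized per channel, and the labeling channel is fitted
with $I(x) = A e^{-kx} + c$ by Levenberg–Marquardt least squares
(log-linear regression start, $k$ bounded positive, offset $c$ for
camera background). The fit window starts at the labeling channel's
half-maximum crossing beyond its peak — the compartment edge — because
the exponential model describes the decay outside the compartment, not
the plateau inside it. Constant or non-convergent profiles are flagged
with their residual instead of returning a rate. The default profile
length for near-focus quantification is 1.5 µm.

Near-focus immunofluorescence is the mean intensity within a sphere
(spheres clipped at the image border are logged), compared between the
two focus classes with a two-sided Wilcoxon rank-sum test; a fully tied
comparison returns p = 1.

The center/periphery partition operates on 2-D maximum-intensity
projection masks. Pixels are ranked by Euclidean distance to the
nuclear edge and the deepest half forms the central region — an exact
equal-area split up to one pixel, with ties at the threshold broken
deterministically by pixel order. On a disk of radius $r$ this
reproduces the analytic inner radius $r/\sqrt{2}$. Nucleus segmentation
itself is out of scope: masks are inputs.

## The synthetic-data generator

The generator exists so every stage can be tested for recovery of known
truth; its defaults define the validation conditions used throughout
the test suite.

**LFQ.** Baselines are $N(25, 2^2)$ log2 units; replicate noise is
protein-specific with prior scale 0.2 (technical-triplicate grade) and
scaled-inverse-chi-square heterogeneity with 12 df, which makes
variance moderation both necessary and estimable. Spiked proteins gain
`effect_log2fc` (default 1.5) in their condition. Dropout is logistic
left-censoring, $P(\mathrm{missing}) = \mathrm{logis}(-a(I - m))$ with
slope $a = 3$ and midpoint $m = 21$: a transition about one log2 unit
wide centred roughly two SD below the mean abundance, the sharp
detection-limit picture that MinProb imputation assumes, yielding ~3%
overall missingness concentrated in the left tail. A shallower curve
would make partially-missing borderline proteins common and imputation
artifacts — not the planted effects — would dominate recovery tests.
Contaminants (5% of background) appear in 60–100% of simulated controls
with counts 16–100 so the contaminant filter has true positives;
presence is binomial over 10 controls, so a filter recovering ~90% of
flagged contaminants is the expected behavior, not a defect. Validation
uses 40 spiked among 2000 background proteins at log2FC = 2 over 20
seeds (precision ≥ 0.9, recall ≥ 0.8), and a 2000-protein null design
for the t-test's size.

**Networks.** Community-structured graphs: within-module pairs get
edges with `p_within` and Beta-distributed scores around 0.8,
between-module pairs with `p_between` and scores around 0.4. Calibration
uses 400 proteins in 5 modules with 50 random sets; enrichment
monotonicity uses module-concentrated sets at increasing
`p_within`/`p_between`.

**Images.** Each molecule is an integrated (per-voxel exact) 3-D
Gaussian with lognormal brightness (CV 0.2) — heavy-tailed and positive,
as smFISH intensities are; foci sum jittered molecules; halos add
$A e^{-kr}$ in 3-D radial distance around halo-positive foci in the
labeling channel, mirroring the exponential decay model fitted
downstream; Gaussian camera noise comes last, clipped at zero.
Validation stacks are 16 × ~100 × ~90 voxels with counts up to 10 at
SNR ≥ 10, decay-rate recovery within 5% noiseless and rate ordering
over 100 noisy seeds.

**What is not emulated:** peptide-level quantification and search-engine
artifacts, match-between-runs correlation structure, batch effects
beyond sample medians, optical aberrations, depth-dependent PSF
variation and deconvolution residues, segmentation errors, and any
biological correlation between a protein's abundance and its network
degree. Passing recovery tests therefore demonstrates correctness of
the estimators under their stated models, not robustness to every
artifact of real acquisitions.

## Reproducibility machinery

Every stochastic function takes an explicit seed; the pipeline derives
per-stage sub-seeds from one global seed by hashing stage labels, so
stages rerun independently give identical results and two runs with the
same configuration and seed produce byte-identical reports (timestamps
live only in the log). Reports and all output tables carry the MD5 hash
of the configuration that produced them; the output directory is
excluded from the hash, since where a run is written does not change
what it computed. TSV with header row, tab delimiter and empty fields
for missing values is the canonical tabular dialect; stacks are
multi-page 32-bit float TIFFs with a JSON metadata sidecar.

## Known limitations

* The moment-matched prior is less efficient than a full ML fit for
  very small protein counts; with fewer than ~50 proteins, `d0`
  estimates are noisy (they stabilize the t only mildly there).
* The decomposition estimator cannot separate overlapping foci whose
  joint intensity is consistent with one larger focus; FISH-quant-style
  mixture refinement would be needed for crowded fields.
* The exponential-fit anchor (half-maximum crossing) is a convention;
  profiles whose compartment edge is not well described by the half-max
  point will bias `k` slightly (the noiseless recovery bias is ~4%,
  within the 5% validation band).
* The signed-rank p saturates at the number of simulated proteomes;
  increasing `n_samples` sharpens p but not the fold.
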