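---
title: "Quantifying ecDNA clustering, nuclear position and per-copy output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ecDNA clustering, nuclear position and per-copy output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdnaspatial)
```

# The scientific question

Extrachromosomal DNA (ecDNA) are circular, centromere-free DNA elements of
roughly 1–3 Mb that carry amplified oncogenes (EGFR, CDK4, PDGFRA, ...) at
high and strongly heterogeneous copy number per cancer nucleus. Two
mechanisms have been proposed for their outsized transcriptional output:
(i) spatial — ecDNA congregate into "hubs", possibly together with large
RNA polymerase II condensates, and the hub environment boosts transcription;
(ii) dosage — each ecDNA copy is transcribed at an ordinary per-copy rate
and the output is simply proportional to copy number. The two hypotheses
make different quantitative predictions about FISH focus geometry and about
copy-number-normalised expression, and this package implements the
statistics that discriminate them.

# The clustering test

## Model and estimator

Foci detected in one nucleus are treated as a 3D point pattern
$x_1,\dots,x_n$ (micrometre coordinates of spot centroids). The spatial
summary is Ripley's K,

$$\hat K(r) \;=\; \frac{V}{n^2} \sum_{i \ne j} \mathbf 1\{d(i,j) \le r\},$$

with $V$ the reference volume, ordered pairs (each unordered pair counts
twice), the inclusive inequality $d \le r$, and **no edge correction**. The
$1/n^2$ normalisation (rather than the textbook $1/(n(n-1))$) is kept
deliberately: the Monte-Carlo null below is evaluated with the *same*
estimator on the *same* volume, so the multiplicative bias $\;(n-1)/n\;$
cancels from the inference entirely; the textbook divisor is available via
`ripley_config(normalisation = "unbiased")` for comparison. Likewise the
missing edge correction affects observed and null K identically and is
absorbed by the simulation-based reference distribution.

## Null model and geometry

The null of *complete spatial randomness* (CSR) is sampled by drawing the
same number of points uniformly in a ball of radius 5 µm
(`bounding_radius`, the null geometry used for every nucleus) and
recomputing $\hat K$ — by default `n_null = 10000` times per nucleus at each
of the radii 0.1–1.0 µm in 0.1 µm steps. Nuclei with 20 or fewer foci are
excluded (`min_foci = 20`, strict), because sparse patterns give the test
essentially no granularity.

## P-values, ties, and the optimistic bias

The per-radius p-value is the one-sided empirical rank
$p_\mathrm{hi} = \#\{K_\mathrm{null} \ge K_\mathrm{obs}\}/N$ (clustering is
high K; dispersion is deliberately not flagged — a significant call
additionally requires $K_\mathrm{obs}$ to exceed the null *median*).
Because $\hat K$ is $V/n^2$ times an integer pair count, observed and null
values live on the same lattice and exact ties are routine, not
pathological. Three tie policies are provided:

* `"conservative"` — $p = p_\mathrm{hi}$, the standard valid empirical
  p-value;
* `"randomized"` — a randomized tie-break that declares significance with
  probability equal to the fraction of tied values falling below the
  $\alpha$ cut position (the exact-test resolution);
* `"optimistic"` (default) — $p = p_\mathrm{lo} =
  \#\{K_\mathrm{null} > K_\mathrm{obs}\}/N$ whenever ties occur, i.e. the
  most favourable rank for the clustering hypothesis.

The optimistic default reproduces the deliberate bias of the source
analysis protocol this package re-implements: when in doubt, err towards
*calling* clustering, so that a negative result is maximally convincing.
The cost is calibration: at sparse radii the expected pair count is below
one, so the event "observed count ties a large null mass" has appreciable
probability while $p_\mathrm{lo}$ is tiny. In our own simulations (200 CSR
nuclei of 40 foci, 1000 nulls each, per-nucleus BH at FDR 0.05 — the
configuration the acceptance script re-runs) the fraction of nuclei with at
least one significant radius is about 0.17 under the optimistic default and
about 0.035 under the conservative policy. Strict type-I control and the
optimistic bias are mutually exclusive for discrete K; users who need
calibrated error rates should set `tie_policy = "conservative"` (or
`"randomized"`), and should interpret optimistic *negative* findings as the
stronger statement.

"Established using the Neyman–Pearson lemma" in the source protocol is
operationalised as this one-sided rank test: for a monotone-likelihood-ratio
alternative (more clustering, larger K) the rank of the observed statistic
is the likelihood-ratio-ordered rejection region; no explicit likelihood is
available for the null-vs-Thomas comparison, so the rank reading is the only
implementable one.

Multiple radii are corrected by Benjamini–Hochberg **within each nucleus**
(each nucleus is one family of 10 tests); per-nucleus families reproduce
per-nucleus significance calls. Scope across a whole cohort can be obtained
by pooling the per-radius p-values yourself with `bh_adjust()` — the
building blocks are exported precisely so the family definition stays
explicit.

When the observed K exceeds every null sample, the stored p is 0 with the
Monte-Carlo resolution bound $1/N$ attached as an attribute; BH uses the
stored 0.

# Distance summaries

`shortest_distances()` computes, per source focus, the centre-to-centre 3D
distance to the nearest target focus (self excluded when the channels
coincide). Distances are between spot centroids — spot diameter is metadata
— and cross-channel summaries are directional, since each source focus
selects its own nearest target: CDK4→PDGFRA and PDGFRA→CDK4 generally
differ. The 200 nm proximity convention uses a strict `<` (as the reference
proportions are printed), while the large-focus (PolII hub) filter retains
diameters `>= 0.5` µm inclusive. Displayed percentages truncate to two
decimals because the reference worked example (4 of 1011 foci → 0.39%) is a
truncation, not a rounding, of 0.39565%. Nuclei with fewer than two
relevant foci yield empty, flagged summaries and are excluded from pooled
cumulative distributions with a count kept in the output attributes. No
2D-projection mode exists: projecting 3D stacks inflates apparent
clustering, so only true 3D distances are computed.

# Erosion-shell radial profiling

`equal_area_shells()` partitions a 2D nucleus mask into five concentric
bins of equal area from the periphery (bin 1) to the centre (bin 5) by
iterative erosion with a 3×3 cross structuring element. The erosion
iteration number orders pixels from peripheral to central; cumulative-area
thresholds $kA/5$ cut that ordering into shells. Two numerical choices
matter:

* **Ring splitting.** A one-pixel erosion ring at the boundary of a
  100 px-radius disc holds ~600 px, i.e. ~10% of $A/5$, so assigning whole
  rings cannot achieve equal areas. When a threshold falls inside a ring,
  the ring is split, ordering its pixels by Euclidean distance to the mask
  boundary; shell areas then match $A/5$ to within one pixel.
* **Anisotropy.** Cross-structuring erosion is an $L_1$-type operation:
  eroding a disc repeatedly shrinks it faster along the axes than along the
  diagonals, so deep shell boundaries are not circles even for a circular
  mask. The area-based construction is unaffected (areas are equal by
  construction), and boundary radii should be read as equivalent-area radii
  $\sqrt{\text{area}/\pi}$, which match the analytic disc values
  $R\sqrt{1-k/5}$ to well under a pixel.

`shell_profile()` sums each channel within each shell and divides by the
DAPI sum in the same shell, correcting radial intensity for chromatin
density; since shells have equal areas, the shell-sum ratio and the ratio
of per-pixel means coincide exactly (both are reported; the difference is
identically zero under equal-area shells). `ratio_profile()` then forms
probe-to-probe ratios (e.g. gene FISH relative to a whole-chromosome
paint), and `shell_trend_test()` applies a Kruskal–Wallis test across
shells over nuclei. Only single-slice 2D analysis is provided, matching the
acquisition the profiling emulates; nuclei touching the image border should
be excluded upstream.

# Dosage analysis

Three independent routes ask whether per-copy output differs between ecDNA
and the chromosomal locus:

1. **Focus-count ratios.** Per nucleus, `rna_dna_ratio` = RNA foci / DNA
   foci, and `ecdna_proportion` = (gene DNA foci − CEN7 foci) / gene DNA
   foci, the centromere count proxying chromosomal copies. If per-copy
   transcription is equal in both compartments, the RNA:DNA ratio is
   independent of the ecDNA proportion — `ratio_proportion_correlation()`
   tests this with Spearman rank correlation. Negative proportions (CEN7
   exceeding gene foci, possible with miscounts) are flagged, never
   clamped.
2. **Per-exon normalisation.** Where the ecDNA carries an internal deletion
   (e.g. the EGFRvIII exon 2–7 deletion shipped as `egfr_exon_groups()`),
   exons split into chromosome-only and ecDNA groups; RNA-seq counts
   normalised by WGS counts per exon are compared between groups by
   Mann–Whitney (`compare_exon_groups()`).
3. **Allele-frequency ratios.** Heterozygous SNPs (control allele frequency
   within 40–60%, inclusive bounds) that lie in expressed exons with at
   least 20 RNA-seq reads give per-SNP RNA/WGS allele-frequency ratios of
   the amplified allele; `af_ratio_analysis()` reports per-gene unweighted
   medians. Equal per-copy transcription predicts medians at 1.

# What the simulators emulate — and what they do not

The point-pattern generators place foci in a 5 µm ball (matching the null
geometry; an elliptical nucleus is deliberately not modelled because the
clustering inference was insensitive to nucleus shape): CSR for the null,
a Thomas process (uniform parents, Poisson(`mean_children`) offspring,
isotropic Gaussian scatter `sigma`, parents not emitted) for hub-like
clustering, doublets at fixed separation for double minutes, and a
dual-channel pattern with a controlled colocalised fraction for two ecDNA
species sharing molecules. Out-of-ball children and partners are resampled,
not clipped, so pairwise-distance structure is preserved; the truncated
Gaussian is sampled exactly in both the small-`sigma` (Gaussian rejection)
and large-`sigma` (uniform-ball proposal) regimes. Each nucleus receives
its own RNG stream split deterministically from the master seed.

The dosage generator draws, per nucleus, 3 chromosome 7 copies and a
negative-binomial ecDNA count (mean 45, size 2 — the strong cell-to-cell
copy-number heterogeneity characteristic of ecDNA amplification), with each
copy independently showing a nascent-transcription focus with probability
0.5 per copy (a bursting-type fraction; it also leaves room for a two-fold
ecDNA boost to remain a probability). Bulk tables use cohort-total copy
numbers: per-exon Poisson counts proportional to copy number (WGS) and to
transcribing-copy rate (RNA), and per-SNP binomial allele counts at Poisson
depths, with the amplified haplotype carrying one chromosomal copy plus all
ecDNA copies.

None of the simulators model optical point-spread functions, photon noise,
spot-detection failures, z-sectioning (a 3 µm imaged section could truncate
the visible z-range; coordinates here fill the full ball), segmentation
errors, or alignment/variant-calling artefacts in the sequencing tables.
Passing tests therefore certify the *statistical machinery* — estimator
correctness, calibration, power, parameter recovery — on idealised inputs,
not the upstream measurement pipeline.

# Problem sizes and numerical conventions

Simulation-based tests and the acceptance script run at reduced but
adequate sizes chosen for precision: 1000-sample nulls (the Monte-Carlo SE
of the null mean is then well below the effects tested; the full analysis
default remains 10,000), 200 CSR nuclei for type-I rates, 50 nuclei for
power, 20–30 replicates for dosage medians and correlations. Distances are
written with 4 decimals (0.1 nm resolution); all interchange files carry
explicit `_um` unit suffixes; coordinates are continuous physical positions,
never voxel indices. Degenerate inputs follow a consistent rule: impossible
requests (negative counts, non-positive radii, separations exceeding the
ball diameter, disconnected masks) raise errors, while legitimate-but-empty
outcomes (no foci, fewer than two relevant foci, all-subthreshold
candidates, an excluded nucleus) return empty, flagged objects so cohort
loops need no special-casing.

# Known limitations

* The optimistic tie policy is anti-conservative by construction (see
  above); calibrated inference requires the conservative or randomized
  policy.
* The erosion-shell boundaries inherit $L_1$ anisotropy from the cross
  structuring element; profiles of strongly elongated nuclei will mix
  radial and axial structure.
* The ecDNA proportion estimator assumes one gene copy per chromosome and
  one focus per molecule; doublet fusion or HSRs bias it.
* The allele-frequency model assumes the amplification derives from a
  single parental allele; mosaic amplification would dilute the predicted
  WGS allele frequencies.
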