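# ecdnaspatial

Spatial statistics and dosage analysis for extrachromosomal DNA (ecDNA)
foci in cancer nuclei.

Extrachromosomal DNA are circular, centromere-free elements (~1–3 Mb) that
carry amplified oncogenes (*EGFR*, *CDK4*, *PDGFRA*, ...) at high,
cell-to-cell-heterogeneous copy number, notably in glioblastoma. A central
mechanistic question is whether their large transcriptional output comes
from spatial organisation — ecDNA clustering into "hubs", possibly at large
RNA polymerase II condensates — or simply from gene dosage, each copy
transcribing at an ordinary per-copy rate. This package implements the
quantitative analyses that discriminate the two, for anyone working with 3D
FISH spot coordinates, nuclear images, or matched WGS/RNA-seq count tables:

* **Clustering** — a per-nucleus 3D Ripley's K test. The estimator is
  `K(r) = V · Σ_{i≠j} 1{d(i,j) ≤ r} / n²` with no edge correction; each
  nucleus's observed K over radii 0.1–1.0 µm is compared against 10,000
  Monte-Carlo samples of the same number of points placed uniformly in a
  5 µm ball, giving one-sided empirical p-values (with explicit handling of
  the ties that discrete pair counts produce), Benjamini–Hochberg
  correction across radii within each nucleus, and a clustering call that
  also requires the observed K to exceed the null median.
* **Distances** — per-focus shortest 3D distances within and between
  channels, proximity fractions at a threshold (e.g. the fraction of foci
  within 200 nm of another species), pooled cumulative distributions, and
  distances to large (≥ 500 nm) PolII foci.
* **Radial position** — equal-area erosion-shell profiles of single-slice
  nuclear images: five concentric bins from periphery to centre, per-shell
  probe intensity normalised to DAPI, probe-to-probe ratios, and a
  Kruskal–Wallis trend test.
* **Dosage** — RNA:DNA focus ratios vs the estimated ecDNA proportion
  `(gene foci − CEN7 foci)/gene foci` (Spearman), per-exon RNA/WGS
  normalised counts compared between chromosomal-only and ecDNA exon groups
  (Mann–Whitney), and RNA/WGS allele-frequency ratios at heterozygous
  amplicon SNPs (40–60% control allele frequency, ≥ 20 RNA reads).
* **Simulators** — CSR, Thomas-clustered, doublet and dual-channel point
  patterns in a bounded nucleus; radially biased images with masks; and
  copy-number-driven count/SNP tables with an optional per-copy ecDNA
  efficiency boost — so every analysis is testable end to end without
  microscopy or sequencing data.

## Worked example

Simulate one nucleus with genuine hub-like clustering (a Thomas process:
5 cluster centres, on average 8 foci each, 50 nm scatter) and test it:

```r
library(ecdnaspatial)

fs <- simulate_thomas_nucleus(n_parents = 5, mean_children = 8,
                              sigma = 0.05, seed = 7)
fs
#> <foci_set> nucleus 'nucleus_1': 48 foci, bounding radius 5 um
#>   channels: EGFR (48)

res <- cluster_test(fs, channel = "EGFR",
                    config = ripley_config(n_null = 1000, seed = 8))
res
#> <ripley_result> nucleus 'nucleus_1': n=48 foci; significant clustering
#>   at 0.1 um, 0.2 um, 0.3 um, 0.4 um, ..., 1 um

round(res$table[1:3, c("radius_um", "observed_k", "null_median",
                       "null_max", "p_value", "q_value")], 4)
#>       radius_um observed_k null_median null_max p_value q_value
#> r_0.1       0.1    53.6325           0   0.4545       0       0
#> r_0.2       0.2    94.0842           0   0.9090       0       0
#> r_0.3       0.3    95.9022           0   1.8181       0       0
```

At 100 nm the observed K (53.6 µm³) exceeds even the most extreme of 1000
uniform nulls (max 0.45 µm³), so the empirical p is 0 (resolution bound
1/1000) and the nucleus is called clustered — exactly what a planted
50 nm-scale hub structure should produce. The distance summaries agree:

```r
s <- shortest_distances(fs, "EGFR", "EGFR")
s
#> <distance_summary> nucleus 'nucleus_1' EGFR -> EGFR: n=48,
#>   mean=0.0467 um, min=0.0163 um
proximity_fraction(s, 0.2)
#> 48 of 48 foci (100.00%) within 200 nm of another focus
```

A CSR nucleus run through the same test yields no significant radius, and
its mean shortest distance sits above 1 µm — the signature reported for
real ecDNA, which motivated the dosage analyses:

```r
tabs <- simulate_dosage_tables(dosage_sim_config(seed = 5, n_nuclei = 40))
ratio_proportion_correlation(tabs$nuclei)[c("rho", "p_value")]
#> $rho      0.192
#> $p_value  0.24        # no correlation: per-copy output equal
af_ratio_analysis(tabs$snps)$gene_medians
#>   gene median_af_ratio n_snps
#> 1 EGFR        0.998715     40   # allele-frequency ratio at 1
```

Under the copy-number-only generative model the RNA:DNA ratio does not
correlate with the ecDNA proportion and the RNA/WGS allele-frequency ratio
sits at 1; rerunning with `p_transcribe_ec = 1, p_transcribe_chr = 0.5`
(a two-fold per-copy boost on ecDNA) drives both diagnostics up — the
package recovers the regime it is asked to detect.

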