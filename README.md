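# condq

Quantification toolkit for nuclear biomolecular condensates and their
consequences in imaging and genomics data. The motivating system is the
synovial-sarcoma fusion oncoprotein SS18-SSX, whose condensates exclude
HDAC1/2 repressor complexes and coincide with enhanced long-range chromatin
contacts at H2AK119ub-marked regions — but every method here is generic to
any condensate marker, query protein, and binned contact data.

For imaging groups, statisticians, and computational biologists who need:

* **Condensate detection/counting** per nucleus from a marker channel
  (threshold at `mean + k·sd`, 8-connected components).
* **Exclusion/enrichment calls** for a query protein: pixel intensities
  sampled inside vs outside condensates, Z-scored per nucleus against the
  full in-mask pixel population, compared by two-sided Wilcoxon rank-sum
  with Holm adjustment across comparisons:
  `Δmedian = median(Z_in) − median(Z_out)`, verdict `excluded` when
  negative and significant.
* **Half-FRAP dip-depth analysis** under a two-compartment exchange model
  (internal mixing rate *k*<sub>int</sub>, external exchange rate
  *k*<sub>ext</sub>):
  *u*(*t*) = 1 − ½(e<sup>−at</sup> − e<sup>−Bt</sup>) with *a* =
  *k*<sub>ext</sub>, *B* = 2*k*<sub>int</sub> + *k*<sub>ext</sub>, dip
  depth *d* = ½[(a/B)<sup>a/(B−a)</sup> − (a/B)<sup>B/(B−a)</sup>];
  regime classification (free diffusion / LLPS / ICBS-like) by one-sided
  Welch t-test against a free-diffusion reference.
* **Long-range Hi-C enhancement**: contacts-per-million normalization,
  per-bin sums of intra-chromosomal contacts at distances > 1 Mb,
  `log2((L_case+ε)/(L_ctrl+ε))` ratios, bin marking at track signal > 40,
  Spearman correlation, marked-vs-unmarked stratification, and pairwise
  class enhancement.
* **Interval operations**: sweep-line Venn partitions, colocalization
  fractions, and aggregate signal profiles at binding sites (BED/bedGraph
  in and out).

Synthetic-data generators with exact ground truth (images, FRAP traces,
paired contact maps, peak sets) make every stage testable without any
external download.

## Worked example

```r
library(condq)

# --- imaging: an excluded query protein (partition coefficient 0.3) ------
cfg  <- sim_image_config(n_nuclei = 4, partition_coefficient = 0.3, seed = 42)
imgs <- gen_nucleus_images(cfg)
detect_condensates(imgs$images[[1]])
#> condensate_labels: 8 condensate(s), 202 labeled px
exclusion_analysis(imgs$images, n_pixels = 30, n_nuclei = 3, seed = 42)
#> exclusion_report: n = 30 px/group, delta_median = -2.614
#>   Wilcoxon p = 1.18e-16 **** -> verdict: excluded
```

30 pixels per stratum drawn across 3 nuclei: the inside sample sits 2.6
whole-nucleus standard deviations below the outside sample, and the
Wilcoxon test calls the query protein excluded from the condensates.

```r
# --- half-FRAP: dip depth and regime -------------------------------------
dip_depth_closed_form(k_int = 1, k_ext = 1)
#> [1] 0.1924501
trs <- gen_frap_traces(sim_frap_config(k_int = 1, k_ext = 1, seed = 42))
ref <- gen_frap_traces(sim_frap_config(k_int = 1, k_ext = 0, seed = 43))
dip <- function(t) dip_depth_estimate(t)$dip_depth
classify_regime(sapply(trs$traces, dip), sapply(ref$traces, dip))
#> $regime      "LLPS"
#> $p_vs_free   6.02e-08
#> $mean_depth  0.2
```

Equal internal and external rates give a dip of 0.19 — inside the LLPS
band (0.125–0.358) and significantly shallower than the free-diffusion
reference (dip 0.5).

```r
# --- Hi-C: planted 2x enhancement on marked-marked pairs > 1 Mb ----------
maps <- gen_contact_maps(sim_hic_config(seed = 42))
hic_enhancement_report(maps$case, maps$control, maps$track)
#> enhancement_report: 300 bins (60 marked)
#>   correlation (spearman): rho = 0.687, p = 3.23e-43
#>   stratified: median log2 ratio 0.228 (marked) vs -0.015 (unmarked), p = 1.55e-32
#>   pair classes (aggregate log2): MM 0.978, MU -0.015, UU -0.008
```

The marked-marked pair class recovers the planted factor
(log2 2 = 1 ≈ 0.978); per-bin ratios at marked bins are diluted by
unmarked partners (expected log2(1 + 0.2·1) ≈ 0.26, observed median 0.23),
and the stratified Wilcoxon test separates marked from unmarked bins.

## Command line

```sh
inst/cli/condq simulate all --seed 1 --out demo/
inst/cli/condq hic --case demo/ss.coo --control demo/control.coo \
    --bins demo/bins.tsv --track demo/h2ak119ub.bedgraph --out demo/
inst/cli/condq peaks venn --a demo/a.bed --b demo/b.bed --out demo/
```

Reports are TSV with a provenance header (version, config hash, seed);
stage verdicts aggregate into `run_summary.json`.

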