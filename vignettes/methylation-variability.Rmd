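---
title: "Methylation variability, CpG density and selection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation variability, CpG density and selection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methvar)
```

## The statistic and the pipeline

The unit of analysis is an array CpG probe with beta-values
$\beta_{js} \in [0,1]$ over individuals $s = 1..n$. Methylation
variability is the sample standard deviation

$$\mathrm{MV}_j = \sqrt{\tfrac{1}{n-1}\sum_s (\beta_{js} - \bar\beta_j)^2},$$

computed only for complete-case probes after excluding sex-chromosome,
SNP-overlapping and cross-reactive probes. The $n-1$ denominator is the
standard unbiased-variance convention; nothing downstream depends on the
choice beyond a constant factor. The cohort itself is balanced by sex
and age: `select_cohort()` takes healthy samples inside an age range and
pairs males to females by greedy nearest-age matching without
replacement (repeatedly take the globally closest remaining pair, ties
broken by younger age then sample ID). Matching algorithms differ in the
tails; the greedy rule was chosen because it is deterministic, easy to
audit, and the MV statistic is insensitive to which of several
near-identical matchings is used. Samples flagged externally (e.g. for
recorded-vs-inferred sex discrepancies) are removed through the
`exclude` argument rather than by guessing a rule.

MV is then related to four overlays, each a module with its own
numerical contract.

### CpG cluster density

Regions are discovered from raw sequence. 200-bp windows at 50-bp steps
are *seeds* when they satisfy the intermediate-density minima (GC
fraction > 0.50 and Obs/Exp CpG ratio > 0.48, with
$\mathrm{Obs/Exp} = N_{CpG} \cdot L / (N_C \cdot N_G)$); touching seeds
merge into maximal spans, each span is re-measured in full and
classified: high-density (HC) when GC > 0.55, Obs/Exp > 0.75 and length
> 500 bp; intermediate (IC) when GC > 0.50, Obs/Exp > 0.48 and length >
200 bp; otherwise the span is dropped and its probes fall to low-density
(LC). All inequalities are strict, so boundary values (GC exactly 0.55)
fail the stricter class. `N` bases are excluded from base counts and
from the effective length inside the ratio, while the reported region
length is the genomic span — this avoids inflating Obs/Exp across
assembly gaps. The window/step sizes are a deterministic, testable
reading of cluster discovery; published island annotations built with
other parameters can be substituted via the precomputed-regions path
(`assign_density()` accepts any sorted non-overlapping region table, and
the CLI takes `--regions`).

Probe classification converts the 1-based probe coordinate to 0-based
and tests containment against half-open `[start, end)` intervals. The
same `findInterval`-based lookup is the single code path for density
assignment and conservation lookup, and it is tested against an
all-pairs brute-force oracle.

### Ancient selection (conservation)

Each probe takes the score of the conservation-track interval covering
it; uncovered probes are dropped and counted rather than scored 0,
because absence of evidence is not a neutral score. Negative scores are
removed (zero is kept), the remainder binned into quartiles, and MV
summarised per quartile. Quantile boundaries use R's default
linear-interpolation rule (`quantile(type = 7)`), bins are left-closed
right-open with the top bin closed; this is stated explicitly so that a
reimplementation can agree bit-for-bit. Degenerate inputs (fewer than
four distinct values, coincident boundaries) are errors, not silent
collapses. The trend is tested with `oneway.test(var.equal = FALSE)`;
"one-way test" is ambiguous between Welch and classical ANOVA, so both
p-values are reported with Welch as the headline (it is the R default
and robust to the strong variance heterogeneity between quartiles).

### Recent selection

The SNP filter is a strict conjunction of the 12 published cutoffs; a
record missing any statistic fails, because the filter models a complete
database table. Two SNP datasets merge by rsid with passing copies
preferred and input order breaking remaining ties; a duplicated rsid
with conflicting coordinates is a consistency error. RSP-CpGs are probes
within `half_window` of a passing SNP. The phrase "a 2000-bp range
around a SNP" admits two readings; the default `half_window = 1000`
takes the total-span reading, by analogy with the promoter case where "a
3000-bp range around the TSS" explicitly meant ±1500. The ±2000 reading
is one argument away.

The group comparison is a Monte Carlo resampling test: the observed
statistic is the mean MV of the RSP probes; the null draws `B` subsets
of the same size uniformly without replacement from the pooled probe set
and the one-sided empirical p is $(\#\{\bar{x}^* \le \bar{x}_{obs}\} +
1)/(B + 1)$. The add-one rule keeps p positive, and zero exceedances at
the default B = 10,000 report p just under $10^{-4}$. Resampling from
the non-RSP complement, or with replacement, are options; the pooled
without-replacement subset null is the default because it is the
permutation-style reading of a "bootstrap comparison" with a
one-directional claim. A Welch two-sample t-test of conservation scores
between RSP and non-RSP probes checks that the two selection overlays
are not proxies for each other.

### Promoter enrichment

Probes within ±1500 bp of a TSS (symmetric, strand-ignored) map to that
gene; a probe inside two windows contributes to both genes. Gene MV is
the arithmetic mean of its probes' MV ("averaged" is the plain reading;
median is an option), one TSS per gene symbol is assumed in the
annotation input. Genes are z-scored with $\mu$ and $\sigma$ the mean
and sample SD of the *gene-level* values — the alternative (probe-level
$\sigma$) only rescales the ranking without reordering it, and the
gene-level choice makes the ranked list self-consistent. Ties in z break
alphabetically so the ranking is reproducible.

The preranked GSEA statistic is the weighted Kolmogorov–Smirnov running
sum: walking down the list, set members add $|z|^w / \sum_{hits}|z|^w$
(weight $w = 1$) and non-members subtract $1/(N - N_{hit})$; ES is the
signed maximum deviation. With only a ranked list available, the null is
gene-set permutation: `n_perm` random same-size sets per set size — and
when $\binom{N}{k} \le$ `n_perm` the implementation enumerates *all*
same-size subsets, making the nominal p exact on small lists (this is
what the toy tests check). NES divides ES by the mean magnitude of
same-sign null ES; FDR q follows the pooled-NES procedure with a
monotone clean-up within each tail. Sets are significant at nominal p ≤
0.01 and FDR q ≤ 0.25 simultaneously, split into high-MV and low-MV
tails. The desk-scale `min_size` default is 3 (the conventional 15 would
empty toy runs); both bounds are configurable.

## The synthetic study

`sim_config()` fixes the study conditions; `simulate_methylome()`
materialises them. Defaults: 50 samples, 5000 probes, a 1-Mb main contig
with 40 planted HC blocks (520–700 bp) and 50 IC blocks (280–460 bp) in
AT-rich background, plus small chrX/chrY contigs so the sex-probe filter
has something to remove. Probes sit at real CpG dinucleotide positions,
stratified (22% HC / 26% IC / rest background) the way arrays oversample
islands. Cluster blocks are generated with class-appropriate base
composition and rejection-checked against their class criteria with a
margin (HC at GC ≳ 0.57, IC ≳ 0.52), because discovery windows can clip
up to ~60 bp at block edges; with the margin every planted block is
recovered by the scanner, which the tests verify.

Beta-values are Beta-distributed per probe with mean $m$ drawn by class
(HC hypomethylated, Beta(2,22); IC intermediate, Beta(3,3); LC high,
Beta(7,2.5)) and target SD

$$s = s_{class}\; \cdot\; 4m(1-m)\; \cdot\; r^{RSP}\; \cdot\;
\big(1 - \lambda\, g/6.18\big)_{g>0},$$

with $s_{class}$ = 0.010/0.030/0.050 for HC/IC/LC, the inverted-U factor
$4m(1-m)$ planting the intermediate-methylation variability peak,
$r = 0.77$ the dispersion shrink inside selected-SNP windows (a ~23%
group-mean MV reduction, the magnitude reported for selection contrasts
in blood methylomes),
and $\lambda = 0.8$ the conservation coupling over scores $g$ drawn
positive for a 40% conserved fraction (uniform on (0, 6.18]; the rest
negative down to −12.36). Dispersion is clamped inside the feasible
region of the Beta family ($s \le 0.8\sqrt{m(1-m)}$); $s = 0$ yields
identical values, a degenerate case the MV tests exercise. 0.1% of
entries are masked missing — enough to exercise the complete-case rule
without gutting the probe set.

Selected SNPs must not confound the density structure: a window around a
probe in a CpG cluster captures tens of low-MV probes, so uniform
anchoring would make the "selected" group low-MV for the wrong reason.
Anchors are therefore allocated per density class proportionally to the
class's effective window count (probes divided by mean window capture)
and drawn inverse-density within class, making window coverage
approximately uniform over probes. Failing SNPs are generated by
perturbing exactly one randomly chosen statistic past its threshold, so
each of the 12 criteria is individually exercised. Gene TSSs anchor at
well-separated probes; the first block of genes forms the planted
high-MV set (promoter-probe dispersion ×2.2), the second the planted
low-MV set (×0.35), and decoy sets are random.

What the generator deliberately does **not** emulate: raw intensity
channels, normalisation or batch structure (upstream of this pipeline's
inputs); linkage between SNPs; realistic genome-scale probe counts
(480k) or the real genome's island landscape; cell-type mixture in the
cohort samples (the composition filter is exercised on a purpose-built
reference panel fixture instead). Passing tests therefore demonstrate
that the machinery recovers planted structure of realistic shape and
magnitude at reduced scale — not that real data would show these
effects.

### A note on calibration under spatial clustering

With class dispersion varying along the genome, a window-defined probe
group is a *cluster sample*: its mean MV has larger variance than the
mean of an equally sized uniform subset, so the resampling test's
iid-subset null is over-dispersed for window groups even when no effect
is planted. This is a genuine property of genomic-window statistics, not
an implementation artefact. The calibration checks therefore use a
cluster-free sparse design (no planted clusters, ~0.6 probes/kb), in
which MV is iid across probes, window membership is exchangeable, and
the empirical p is uniform under the null — which the tests confirm. On
clustered designs the planted-effect contrast is made detectable by
scale instead, and the composition-balanced anchoring above keeps the
realized contrast near the planted 23%.

## Numerical choices, in one place

- Strict inequalities exactly as printed for all class and filter
  thresholds; boundary values fail.
- Quantiles: `type = 7` everywhere (quartiles and deciles share one
  implementation); degenerate boundaries error.
- MV: two-pass mean/SD agrees with `apply(x, 1, sd)` to 1e-12 relative;
  fewer than 2 samples is an error, as is any missing value (the
  complete-case precondition is enforced, not patched).
- Bootstrap: add-one empirical p; deterministic given `seed`;
  `B >= 100` enforced.
- GSEA: exhaustive subset enumeration replaces sampling whenever
  feasible at the requested `n_perm`; z-ties break alphabetically;
  whole-list and out-of-size sets are skipped with a warning.
- Cell-composition flags: per-probe two-group pooled-variance linear
  model (equivalent to an equal-variance t-test) at p < 1e-07 and
  |Δβ| > 0.05 against the PBMC group; report-only by default, since the
  headline analysis proceeds uncorrected. An empirical-Bayes moderated
  fit would shrink the variance estimates; with ≥ 5 samples per purified
  group the rankings agree closely, and the plain model keeps the
  contract exactly testable.
- All machine outputs (TSV/JSON) are timestamp-free and byte-identical
  across reruns with the same config and seed.

## Problem sizes used by the tests

The default synthetic study (50 samples × 5000 probes, 1-Mb contig) runs
the full pipeline in a few seconds and anchors the end-to-end
assertions. Replicate batches use reduced designs: 700-probe / 200-kb
studies for single-property checks, 100 replicates at
`gerp_mv_slope = 0` for the conservation null, and 200 cluster-free
250-probe replicates for bootstrap calibration (B = 999 per replicate).
These sizes were chosen so each planted pattern is detected with wide
margins while a full test run stays in the tens of seconds.

## Limitations

- Region discovery is a deterministic approximation to published island
  annotations; use the precomputed-regions path for exact external
  annotations.
- The resampling null ignores spatial autocorrelation (see the
  calibration note); on real, clustered genomes the reported bootstrap p
  for window groups is anti-conservative to an unknown degree.
- The cohort matcher optimises greedily, not globally; with heavily
  skewed age distributions a global matching could retain more pairs.
- Gene-set FDR follows the pooled-NES heuristic of the standard
  preranked tool; it is not a formal FDR guarantee at small `n_perm`.
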