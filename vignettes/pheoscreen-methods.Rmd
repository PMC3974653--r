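---
title: "Methods: qHTS curve triage, cross-species target correlation, and median-effect synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qHTS curve triage, cross-species target correlation, and median-effect synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pheoscreen)
```

`pheoscreen` implements the analysis chain of a drug-repurposing screen in
a metastatic pheochromocytoma cell model: quantitative high-throughput
screening (qHTS) with concentration–response curve classification and hit
triage, a cross-species expression meta-analysis bridging murine screen
hits to human tumor profiles, a drug–target network with
eccentricity-centrality hub ranking, and Chou–Talalay median-effect
quantification of drug combinations. Every stage can be exercised on
synthetic inputs with planted ground truth, so the whole pipeline is
testable without any external data.

## The qHTS model

Each library compound is tested as an 8-point titration rather than at a
single dose. The compound stocks are prepared as a 1:2.236 serial dilution
series; cells see alternate members of that series, so consecutive
*tested* concentrations differ by a factor of $2.236^2 = 5.000$ and the 8
points span 0.589 nM–46 µM (reported as "0.5 nM to 46 µM").
`qhts_concentrations()` encodes this geometry.

**Normalization.** Raw luminescence reads are scaled per plate against the
control columns: DMSO-only wells define 0% (basal) and positive-control
wells (doxorubicin at a fully cytotoxic dose) define 100% inhibition,

$$y = 100\,\frac{\mathrm{read} - \tilde{c}_\mathrm{DMSO}}
{\tilde{c}_\mathrm{pos} - \tilde{c}_\mathrm{DMSO}},$$

with $\tilde{c}$ a control median — the median rather than the mean so a
few bad control wells cannot shift the scale. Normalization is affine, so
it is idempotent on already-normalized data with ideal controls. A control
window below `window_tol` raises a degenerate-window error rather than
producing unbounded values.

**Curve fitting.** `fit_4pl()` fits the four-parameter logistic

$$y(x) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (\mathrm{IC}_{50}/x)^{h}}$$

by Levenberg–Marquardt least squares. The optimizer is started from a
deterministic grid (six log-spaced IC50 seeds spanning the tested range
× two Hill seeds); the start with the lowest residual sum of squares
wins, and no randomness enters the fit. IC50 and Hill are optimized on the
log scale, which keeps both positive without constrained optimization.
Failure is reported through a `converged` flag, never an exception; a fit
whose residuals are numerically zero is accepted as converged even when
the optimizer exhausted its iteration budget wandering a flat residual
manifold (this happens for single-point-active curves, where several
parameter combinations reproduce the data exactly). Efficacy is
$|\mathrm{top}-\mathrm{bottom}|$ capped at the observed response window,
so an extrapolated asymptote cannot claim more effect than the data show.

**Curve classes.** The classification follows the standard qHTS scheme:
class 1.1/1.2 are complete curves (both asymptotes) with efficacy ≥ 80% /
< 80%; 2.1/2.2 are incomplete curves (one asymptote) with the same
efficacy split; class 3 is activity at only the highest concentration or a
poor fit; class 4 is inactive. The published description leaves three
notions undefined numerically; `qhts_config()` exposes each as a
parameter:

* *asymptote present* — the fitted plateau is supported by ≥ 2 tested
  concentrations whose model response lies within 10% of the plateau
  (fractions of the fitted window);
* *poorly fit* — $r^2 < 0.5$;
* *single-point activity* — exactly one response, at the top
  concentration, beyond 3× the robust noise level (1.4826·MAD of the
  low-concentration responses, floored at 1 percentage point so noiseless
  data does not divide by zero).

Decision order is 4 → 3 → completeness → efficacy split, making the
classification total, mutually exclusive and exhaustive.

**Triage.** Actives are compounds in classes 1.1–2.2 with efficacy
strictly above 60%; class 4 is inactive; everything else (class 3, and
fitted curves below the efficacy cut) is inconclusive. The published hit
list contains class-1.2 compounds with fitted efficacy just under 60%,
suggesting the original triage may have used the maximal *observed*
response instead of the fitted window; both readings are implemented and
`qhts_config(triage_efficacy = "observed")` switches to the alternative.
The fitted-efficacy rule is the default because it is the literal wording.
Hits are ranked by curve-class confidence (1.1 < 1.2 < 2.1 < 2.2), then
ascending IC50, ties broken by compound id so the ordering is
deterministic. Category enrichment is the percentage of actives per
therapeutic category, flagged above 20%.

## What the synthetic screen emulates

`gen_screen_library()` plants one true curve per compound. The class
windows were chosen once, from the geometry of the tested range, so each
planted class is unambiguous under its own definition:

| class | IC50 (µM) | Hill | planted efficacy (%) |
|---|---|---|---|
| 1.1 | 0.02–2 (log-uniform) | 1.8–3 | 85–100 |
| 1.2 | 0.02–2 | 1.8–3 | 62–78 |
| 2.1 | 10–22 | 1.5–2.5 | 85–105 |
| 2.2 | 10–22 | 1.5–2.5 | 62–78 |
| 3 | 60–80 | 3–5 | 35–50 (top point only) |
| 4 | — | — | 0 (flat) |

Complete-curve IC50s sit far enough inside the range that both plateaus
get ≥ 2 supporting points; incomplete-curve IC50s sit just above the range
so only the rising limb and at most the top point approach the asymptote;
class-3 IC50s are beyond the range with steep slopes so only the top
concentration responds. Efficacies are planted ≥ 2 percentage points from
the 60/80 thresholds, which makes noiseless classification recovery
deterministic. Noise is additive Gaussian on the normalized scale
(default sd 3% of the signal window, a typical luminescence CV);
`gen_plate_reads()` maps responses into raw counts anchored by the control
levels (defaults 2000/200). The default library mixture
(`paper_class_mix()`) reproduces the published triage composition: 76
actives (split 8/14/11/17 as in the printed top-50), 269 inconclusive,
3481 inactive out of 3,826.

The generator does **not** emulate plate edge effects, liquid-handling
artifacts, luminescence photophysics, compound carry-over, or the 24 h vs
48 h time-point contrast; passing tests demonstrate correctness of the
analysis chain under the planted model, not robustness to those real-world
artifacts.

## Cross-species meta-analysis

Both expression matrices are standardized gene-wise (`zscore_genes()`:
each row to mean 0, population sd 1; zero-variance rows are zeroed and
flagged), then merged on the intersection of gene symbols
(`merge_common_genes()`), with murine symbols uppercased into the human
namespace — an explicit ortholog table can override the case mapping.

Row standardization within each data set removes every gene's location, so
any statistic built on per-data-set gene means would be identically zero
if computed from the z-scores themselves. The package therefore retains
each gene's pre-standardization mean as an attribute of the z-scored
matrix, and the two scale-dependent steps — the <2-fold filter and the
cross-data-set correlations — run on those stored log2-scale means. The
fold-change filter keeps genes with $|\bar{a}_g - \bar{b}_g| <
\log_2(\mathrm{threshold})$ and is monotone in the threshold. Per drug,
`drug_target_correlation()` computes the Pearson correlation between the
two data sets' gene-mean vectors over the drug's mapped targets; this is
the only construction that is well defined when the two data sets have
different sample counts. Drugs with fewer than 3 mapped targets are
reported as undefined rather than given an unstable correlation. The
"number of highly correlated genes" per drug has no published definition;
it is exposed as a threshold on each gene's standardized agreement product
with no default claim.

`gen_expression_pair()` draws shared gene means from a bivariate normal
with correlation `rho` (sd 0.6 on the log2 scale), adds per-sample noise
(sd 0.08, which reproduces replicate correlations around 0.98), and gives
a configurable *divergent* fraction a cross-data-set shift of ≥ 1.5 log2
units — these are the genes a 2-fold filter removes. At the published
scale (1,753 shared target genes, 18% divergent) the filter keeps ≈ 1,440
genes whose gene-mean correlation recovers `rho`; the generator's `rho`
default of 0.86 matches the published overall correlation. The published
per-accession values themselves are reproducible only with the original
microarray series, which the package deliberately does not download.

## Drug–target network

The network is undirected and unweighted (nothing in the source defines
direction or weights): one node per drug and per target gene, one edge per
(drug, target) pair. The published "connected node" rendering, in which
all targets of each drug reach all other drugs, is available behind
`connect_targets_to_all_drugs = TRUE` (gene→other-drug edges; the default
is off because the published edge count equals the plain bipartite count).
The published node count (2153) exceeds 22 drugs + 2129 genes by two; the
package reports its own counts (2151) rather than forcing agreement.

Eccentricity centrality: $s(v) = 1/\max_u d(v, u)$ with unweighted
shortest paths. On disconnected graphs the maximum runs over the node's
connected component (the global definition would be infinite), and
singleton nodes are flagged undefined. Hubs are the top-*n* nodes by
score, ties broken by degree then node id — the original plugin's
tie-breaking is unspecified, so the package picks a deterministic rule.
Gene-set subnetworks are induced subgraphs on the matched genes plus every
drug retaining at least one *target* edge into them; extraction is
idempotent. Gene sets come from plain GMT files instead of a live pathway
service, so results are version-pinned and reproducible offline.

## Median-effect synergy

Single-drug response follows the median-effect equation $f_a/f_u =
(D/D_m)^m$, fitted as a straight line in $\log_{10} D$ (least squares;
the line's correlation coefficient `r` is reported as the usual quality
measure). Fraction-affected values are clipped to $[10^{-6}, 1-10^{-6}]$
with a warning, since 0 and 1 are unrepresentable on the logit scale. The
dose producing effect $f_a$ is $D_x = D_m (f_a/(1-f_a))^{1/m}$, strictly
increasing in $f_a$. For a dose pair the combination index uses the
mutually exclusive form

$$\mathrm{CI} = \frac{d_1}{D_{x,1}} + \frac{d_2}{D_{x,2}},
\qquad \mathrm{DRI}_k = D_{x,k}/d_k,$$

so $\mathrm{CI} = \sum_k 1/\mathrm{DRI}_k$ holds exactly for every emitted
row. Calls follow the bands used in the source study: synergistic below
0.8, additive 0.8–1.2, antagonistic above 1.2 (the source prints the
antagonism bound with an inverted inequality, an evident typo given the
additivity band). The analysis is unit-agnostic — CI and DRI only involve
dose ratios — and the bundled combination fixture records doses in nM,
where the printed dose/IC50 multiples are self-consistent.

A constant-ratio combination report's DRI columns imply, row by row, the
single-drug dose producing each row's effect ($D_x = \mathrm{DRI}\times
d$). `median_effect_from_dri()` fits the median-effect line through those
implied points, recovering the single-drug parameters the original
analysis used without access to its raw single-drug curves. On the
bundled combination table the implied points are collinear to four
decimals ($r = 1.0000$ for both drugs), and the recomputed CI column
matches the printed one within 0.001 — a much tighter reconstruction than
forcing the single-drug $D_m$ to the rounded prose IC50s, which is
inconsistent with the printed DRIs (it would require a negative slope for
one drug on the sub-IC50 rows).

`gen_combination_assay()` inverts the CI relation: given planted single
drug curves and a target CI, it solves $d_1/D_{x,1}(f_a) +
d_2/D_{x,2}(f_a) = \mathrm{CI}$ for $f_a$ at each ratio-preserving dose
pair (the left side is strictly decreasing in $f_a$, so the root is
unique), then adds Gaussian noise. Noiseless recovery is exact; at 1%
noise the per-replicate recovered CI is taken as the median across the
five-level design, because the logit transform amplifies fraction-affected
noise near the ends of the effect range and single extreme rows are
correspondingly noisier.

## Numerical choices and degenerate inputs

* 4PL optimizer: `minpack.lm` Levenberg–Marquardt, 12 deterministic
  starts, `maxfev = 5000` (incomplete curves traverse a shallow
  IC50–asymptote valley and need the budget); equal-response series yield
  efficacy ≈ 0 and land in class 4.
* Classification thresholds (60, 80, 30% efficacy floor, $r^2$ 0.5, 3×
  noise, 10% plateau tolerance) all live in `qhts_config()`; efficacy
  comparisons are strict exactly as worded (> 60, ≥ 80).
* Z-scores use the population sd; single-sample matrices are rejected.
* Fold-change thresholds ≤ 1 are rejected; empty gene intersections raise
  an error carrying the per-side gene counts.
* Combination-index inputs with non-positive equivalent doses are
  rejected; CI classification is undefined for CI ≤ 0.
* All generators take explicit integer seeds, use a private RNG stream,
  and restore the caller's random state; identical seeds give
  byte-identical outputs.

## Problem sizes used by the test suite

The packaged checks run screens of 500 compounds (noiseless and at 3%
noise) for parameter/class recovery, 200 seeded replicates per planted CI
level for synergy calls, 100 random graphs of up to 100 nodes against a
brute-force BFS oracle, and 20 replicates of the 1,753-gene expression
pair for the meta-analysis contract. These sizes were chosen as the
smallest at which the recovery statistics are stable; the full published
scale (3,826 compounds) is exercised by the `analysis/` drivers.

## Known limitations

* The activity triage on real screens depends on the fitted-vs-observed
  efficacy reading discussed above; both are implemented but only one can
  be the default.
* Curve-class recovery claims hold under the planted 4PL + Gaussian model;
  bell-shaped (autofluorescent/cytoprotective) responses are outside the
  model and would be classified by their best 4PL approximation.
* The meta-analysis treats uppercased murine symbols as human orthologs
  unless an ortholog table is supplied; paralog families collapse
  incorrectly under that rule.
* Eccentricity is computed per component; comparing scores across
  components of very different sizes is not meaningful.
* Only constant-ratio, two-drug combination designs are supported.
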