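---
title: "Gender-stratified expression analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gender-stratified expression analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Sporadic Parkinson disease shows epidemiological and clinical gender
differences, and expression profiling of nigral dopamine neurons must work
with very small, unbalanced designs: a few laser-microdissected samples per
gender-by-disease cell (here 3 female controls, 3 female PD, 6 male
controls, 7 male PD). At that scale single-gene inference is noisy and the
informative questions are comparative: which genes and pathways are
deregulated in male PD, in female PD, in both, and how stable are those
calls to the significance gate. stratade implements that comparative
workflow end to end, with a synthetic-data generator that plants known
truth so every stage can be scored.

## Differential expression: SAM

For a two-group contrast with samples A and B, the per-probe statistic is

$$d_i = \frac{\bar x_{iB} - \bar x_{iA}}{s_i + s_0},\qquad
s_i = \sqrt{\left(\tfrac{1}{n_A}+\tfrac{1}{n_B}\right)
\frac{\sum_A (x-\bar x_A)^2 + \sum_B (x-\bar x_B)^2}{n_A+n_B-2}},$$

the pooled-variance t statistic moderated by the fudge factor $s_0$. $s_0$
is the percentile of the $s_i$ that minimises the coefficient of variation
of the median absolute deviation of $d$ across 100 quantile windows of
$s$ — the standard recipe that stops low-variance probes from dominating
the tails. With $s_0 = 0$, $d$ is exactly the pooled t (a unit-tested
identity, as is $F = t^2$ against the ANOVA module).

The null is built by permuting group labels: exhaustively over all
$\binom{n_A+n_B}{n_B}$ distinct assignments when fewer than the requested
1000 exist (always the case for the within-gender contrasts here),
otherwise a seeded random sample. Per-probe p-values pool the null across
probes and permutations with add-one smoothing,
$p = (1 + \#\{|d^0| \ge |d|\})/(1 + \#d^0)$.

q-values use SAM's delta thresholding: observed order statistics
$d_{(i)}$ are compared with their null expectation $\bar d_{(i)}$ (the
mean of per-permutation sorted d); for each threshold $\Delta$ the
asymmetric cutoffs give a called set, and

$$\widehat{FDR}(\Delta) = \pi_0\,
\frac{1 + \mathrm{median}_b\,\#\{d^0_b \text{ beyond cutoffs}\}}
     {1 + \#\text{called}},$$

with $\pi_0$ estimated from the fraction of observed d inside the null
interquartile range. A probe's q is the minimum $\widehat{FDR}$ over the
thresholds at which it is called. Two numerical choices matter:

* **Delta grid.** Quantiles of the observed deviations concentrate where
  nothing interesting happens; the grid therefore also includes a uniform
  sweep up to the maximum deviation, so the FDR curve is resolved in the
  tail where the cutoffs actually sit. Without this, q-values jump across
  the 5% gate and sensitivity on planted data halves for some seeds.
* **Add-one smoothing of the FDR numerator/denominator.** The raw median
  null call count is 0 at extreme thresholds (more than half the
  permutations have no exceedance), which would hand the top-ranked probe
  q = 0 even on pure-null data. The same smoothing already used for p
  removes that degenerate zero while leaving calibrated regions untouched
  (measured: mean null false-discovery proportion drops from 0.55 to 0 over
  20 null simulations; planted-data sensitivity 0.92 at realized FDP 0.04).

A "median" vs "90th percentile" null summary is selectable; median is the
default. Gene lists gate conjunctively: q < 0.05 (FDR < 5%) **and**
permutation p < 0.01 (stringent) or p < 0.05 (relaxed). Reading the two
gates conjunctively is an interpretation — the source workflow states the
two thresholds without specifying their combination — and it guarantees
the stringent list nests inside the relaxed one.

## Batch removal and QC

Batch effects are removed per probe by the additive fixed-effects model
`log2 expression ~ disease + gender + batch`, subtracting the fitted batch
component re-centred to preserve the per-probe grand mean. This is the
minimal model consistent with "ANOVA-based batch removal"; interactions
are deliberately excluded (unidentifiable at these sample sizes). The
operation is idempotent and exact for truly additive shifts; if batch is
aliased with the class terms the aliased part is left uncorrected with a
warning rather than silently absorbing disease signal. PCA (on per-probe
z-scores by default, raw log2 optionally) plus a mean-silhouette helper
provide the before/after QC.

## Fold changes, collapsing and the merged matrix

Fold changes are ratios of linear-scale group means, signed: $+r$ for
$r \ge 1$, $-1/r$ otherwise, so a 2-fold drop prints as −2 and
$|FC| \ge 1$ always. Genes with several probes collapse by converting each
signed FC to a ratio, averaging the ratios arithmetically, and converting
back — probes at −2.1 and +1.3 give $((1/2.1) + 1.3)/2 = 0.888 \to$ −1.13.
Averaging in log space instead would give −1.27 and fails that worked
example; ratio space is therefore the contract.

The merged matrix (genes × contrasts) stores collapsed FCs with 0 reserved
as the "absent from that list" sentinel — safe because any list member has
$|FC| \ge 1$. Overlap partitions enumerate membership regions exactly
(checked against brute-force set algebra), with per-list up/down splits and
a configurable >1.5-fold cut-off, and can report region sizes as
percentages of a reference total.

Gender status compares the male and female disease contrasts at both
stringencies: M / F / MF per stringency, then male-specific,
female-specific, shared, or stringency-dependent across them. Overlap
partitioning and classification operate at gene level after collapsing by
default (probe-level lists can be passed unchanged when probe resolution
is wanted).

## Enrichment, anchors and gene-term networks

Over-representation of a size-K set in a size-n list from a size-N
universe with overlap k is the hypergeometric upper tail
$P(X \ge k)$ — the one-sided Fisher exact test, validated by exhaustive
enumeration of all draws for every configuration with $N \le 12$. The
universe is all collapsed genes measured on the platform (standard ORA
practice), not the union of the lists; set members outside it are dropped
with a count. Raw p at $\alpha = 0.05$ is the default significance notion
(no multiplicity correction was specified for the source workflow);
Benjamini–Hochberg per column is available.

Anchor restriction keeps the sets significant in both an anchor column
(the all-samples contrast) and a target column (one gender's contrast) —
the comparative step that pins gender-specific pathway patterns to the
overall disease signal. Gene-term association networks are strictly
bipartite gene–term graphs over selected terms; "multi-term genes" are
those with degree ≥ 2. Term selection ships as labels (e.g. oxidative
phosphorylation, apoptosis, synaptic transmission, transmission of nerve
impulse), since stable accessions depend on the annotation release.

## Key genes and qPCR validation

The key-gene table conjoins four externally curated boolean evidence flags
(pathway-level enrichment membership; disease-pathway association; prior
expression-study support; genetic/GWAS support) with presence in at least
one contrast list, then attaches the five fold-change columns and the
gender status. Evidence is treated as opaque annotation with provenance —
no live database mining.

qPCR quantification is plain 2^−ΔCt with ΔCt measured against the
same-sample endogenous control (GUSB in the motivating assay): replicates
aggregate by mean Ct, cells with replicate SD > 0.5 cycles are flagged
(optional furthest-replicate drop, never silent), the reference gene is 1
in every sample by construction, and genes tier into high/medium/low by
tertiles of mean relative expression. Cross-platform concordance pairs
per-sample 2^−ΔCt values with per-gene array z-scores and reports Spearman
correlation plus direction-of-change agreement. No amplification-efficiency
correction is attempted (2^−ΔCt assumes perfect doubling).

## The synthetic world

`simulation_config()` defaults state the emulated design: 3/3/6/7 samples
across female/male × control/PD; per-gene baselines from N(7, 2) log2
units (array-intensity spread); i.i.d. Gaussian noise with SD 0.35 log2
(the planted-study noise level used throughout the calibration suites);
an additive per-batch, per-gene shift with SD 0.5 log2 across 2 batches
dealt round-robin within each group so batch is never confounded with
class; surplus probes assigned to random genes with probe offsets of SD
0.25 to exercise collapsing. Planted effects are log2 shifts applied to
the PD samples of the targeted gender(s); planted enriched sets draw a
configured fraction of members from the planted DE genes. Ct tables follow
Ct = 30 − log2(expression) + noise, one cycle per 2-fold, so 2^−ΔCt
recovers planted ratios exactly in expectation.

What the generator does **not** emulate: probe-sequence/hybridisation
physics, intensity-dependent variance, missing values, correlated gene
modules, or annotation ambiguity. A green end-to-end test therefore
establishes that the statistical machinery recovers planted additive
structure at realistic noise — not that it is robust to every artefact of
real arrays.

One structural property of the stated design is worth recording: an effect
confined to the 3 female PD samples inflates the within-group variance of
the pooled all-samples contrast proportionally to the effect itself, so
the pooled d statistic saturates below significance for *any* effect size
— purely female-specific genes are invisible to the all-samples list. This
mirrors the motivating study's observation that female PD showed little
enrichment against the all-samples anchor. Consequently the end-to-end
recovery test plants enriched sets drawing on the full DE pool (as the
generator contract states) rather than on single-gender pools, which could
never pass an all-samples anchor for females in this design.

## Known limitations

* SAM here is two-class unpaired only; no paired, multiclass or survival
  variants, and no moderated-t (eBayes) alternative.
* The permutation null is label-exchangeable; heteroscedastic designs
  violate it mildly.
* q-values depend on the delta grid resolution; the shipped grid (quantile
  plus uniform, 100 points each) is deterministic but not adaptive.
* The ANOVA is main-effects-only; disease×gender interactions are out of
  reach at these sample sizes.
* Enrichment ignores the GO DAG (no true-path propagation) and does not
  implement running-sum GSEA; a second collection can be fed through the
  same Fisher machinery instead.
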