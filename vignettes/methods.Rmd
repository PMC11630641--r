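---
title: "Methods: absolute copy numbers, qFlow validation and paired differential analysis"
author: "neutrocopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute copy numbers, qFlow validation and paired differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrocopy)
```

# Scope

neutrocopy implements the quantitative core of a low-input neutrophil
proteomics workflow: converting protein-level DIA intensities from as
few as 1000 cells into absolute copies per cell, validating those
estimates with an independent antibody-titration flow-cytometry
pipeline (qFlow), paired differential expression between conditions
sampled from the same subjects, detection-based enrichment for
presence/absence patterns, and ontology-aware curation of
over-representation results. Everything upstream of the protein-level
intensity table (acquisition, search, peptide-to-protein roll-up,
run-level normalisation) is treated as a black box whose output this
package consumes.

# Absolute copy numbers

Two normalisations convert a protein's MS intensity $I_i$ into copies
per cell; both assume intensity is proportional to protein mass
(MaxLFQ-style protein intensities).

**Total protein approach.** Each protein receives its share of the
cell's total protein mass $M$:
$$c_i = \frac{I_i}{\sum_j I_j}\cdot\frac{M\,N_A}{\mathrm{MW}_i}.$$
The estimate is exactly mass-conserving
($\sum_i c_i\,\mathrm{MW}_i/N_A = M$ over detected proteins, a tested
invariant at $10^{-9}$ relative tolerance) and invariant to any global
rescaling of the sample. The denominator $\sum_j I_j$ is taken after
contaminant removal, so reagent-derived signal does not dilute the
estimates.

**Proteomic ruler.** The summed histone signal stands in for the fixed
DNA mass per diploid cell $m_\mathrm{DNA}$:
$$c_i = \frac{I_i\,N_A\,m_\mathrm{DNA}}{\mathrm{MW}_i \sum_{h\in H} I_h}.$$
This needs no total-mass assumption but fails when no histone is
detected, in which case `proteomic_ruler_copies()` raises a
`ruler-unavailable` error and the caller may fall back to the total
protein approach.

**Per-cell constants.** The package ships working defaults rather than
measured constants: 20 pg protein per human neutrophil (anchored to a
roughly 300 µm³ cell volume and typical cellular protein density),
mouse at 20/1.8 pg to preserve the ~1.8-fold human:mouse protein-mass
ratio, and 6.5/6.0 pg of diploid DNA. Absolute copy levels scale
linearly with these choices; correlations and ratios between methods or
species do not. All of them live in `species_profile()` and should be
replaced by measured values where available.

**Abundance classes.** Proteins are classed high (> 5×10⁵ copies),
medium or low (< 10⁴). The boundaries are printed as strict
inequalities for the outer classes, so medium is the closed interval
[10⁴, 5×10⁵] — a deliberate tie-break making every quantified protein
fall in exactly one class. The top-k share (`topk_share()`) breaks ties
at rank k by protein id so repeated runs agree.

# The qFlow pipeline

Antibody titrations (7-point two-fold dilution, 1000 → 15.63 ng per
test) are fitted with the exponential saturation model
$$y = y_0 + A e^{R_0 x},\qquad A < 0,\ R_0 < 0,$$
by bounded Levenberg–Marquardt least squares. The conventional
initialisation ($y_0 = \max y$, $A = R_0 = -1$) is badly scaled for
ng-range $x$, so the fit is multi-started from that point and from a
data-scaled start ($A = -(\max y - \min y)$, $R_0 = -3/\max x$) and the
lowest-RSS converged fit wins. A series whose Spearman correlation of
signal with amount is non-positive is rejected as having no saturation
trend rather than fitted.

The antibody amount that saturates the target is solved in closed form
from the fitted parameters:
$$x^\* = \frac{\ln\big((1-f)\,y_0 / (-A)\big)}{R_0},$$
with target fraction $f = 0.9995$ by default, i.e. 99.95% *of the
plateau* $y_0$ — we read "of the initial value" as the fitted plateau,
not the dynamic range; the distinction only matters for curves far from
saturation at $x=0$. A spreadsheet-style iterative solver (Goal Seek)
approximates exactly this root, so the closed form is used in
production and a bisection root-finder serves as the cross-check oracle
in the tests ($10^{-8}$ relative agreement over 1000 random valid
parameter sets). If $(1-f)y_0 \ge -A$ the curve already starts above
target and 0 is returned with a warning; amounts beyond the largest
titrated dose carry an extrapolation warning.

Fluorescence is converted to molecules through PE-calibration beads:
ordinary least squares of $\log_{10}(\mathrm{PE})$ on
$\log_{10}(\mathrm{MdnFI})$ — regressed in this direction so prediction
needs no inversion — then
$$\mathrm{copies} = 10^{\,a\log_{10}(\mathrm{MdnFI}) + b}\times
\mathrm{F{:}P},$$
with the antibody lot's F:P coupling ratio applied multiplicatively
(default 1). The permeabilization loss factor
$L = \mathrm{MdnFI}_\mathrm{unfixed}/\mathrm{MdnFI}_\mathrm{fixed/perm}$
upscales the combined surface+intracellular plateau before conversion.
`quantify_target()` chains these stages and reports every intermediate;
in the noise-free limit the whole chain inverts the generators exactly
(tested at $10^{-6}$ relative).

Fold differences between qFlow and MS estimates use the directionless
convention $\max(a,b)/\min(a,b)$ reported *truncated* to one decimal:
truncation, not rounding, is the unique one-decimal rule consistent
with reference value pairs whose raw ratios are 1.47 and 1.89 but are
reported as 1.4- and 1.8-fold. The raw ratio is pre-rounded at the 6th
decimal so floating-point representation cannot flip a truncation at an
exact boundary (1.2/1.0 stays 1.2).

# Paired differential analysis

Proteins enter the test only through `completeness_filter()`:
quantified in every replicate of every condition with ≥ 2 unique
peptides. No imputation is performed — missing values mean "not
detected" and the filter removes them from the testing population,
which is why a separate detection-based rule (below) exists. Per
protein, subject-wise differences of log2 intensities give
$\mathrm{log_2FC} = \bar d$, $t = \bar d/(s_d/\sqrt n)$ and a two-sided
p from $t_{n-1}$. Significance is called on raw p < 0.05 together with
$|\mathrm{log_2FC}| \ge 1$ (the volcano convention); BH-adjusted q
values are reported alongside but do not gate the call. Zero-variance
difference vectors have an undefined t statistic; they are flagged and
excluded from significance rather than given p = 0.

`detection_enrichment()` captures proteins the filter removed: enriched
in one condition when detected in at least half of its replicates
(`ceiling(n/2)`) and in strictly fewer than half (`< n/2`) of the
other's. Requiring half — not full — detection in the enriched
condition is an interpretation choice: it keeps proteins with one
missing replicate in the enriched group, which matches how
presence/absence candidates behave in low-input data.

# Enrichment and term curation

The over-representation stand-in is the one-sided hypergeometric tail
$P(X \ge k)$ over a user-supplied universe, BH-adjusted across the
tested terms. Curation then merges enriched *direct* descendants into
their parents: the parent pools the union of its own and its direct
children's overlap genes (clipped to the universe), the children's rows
are removed and recorded in `merged_children`, and gene counts are
recomputed as union cardinalities. Three deliberate semantics:

* only direct `is_a` edges are honoured (`part_of` is ignored, and a
  grandchild whose intermediate term is absent does not merge);
* genes travel at most one edge — in an enriched chain A ← B ← C, B
  merges into A with its pre-merge genes, and C keeps its own record
  because its direct parent no longer exists as an independent term;
  this keeps the operation idempotent, which is tested;
* each surviving term keeps its own p/q — merging affects counts only,
  and the final ranking is by descending pooled gene count with ties
  broken by ascending q then term id.

BH filtering happens on the un-merged term list, before merging and
ranking.

# Synthetic data: what it emulates, and what it does not

The generators produce every input with the structure the analysis
assumes, so all guarantees can be tested end to end without external
data:

* copies per cell are log-normal (default $\sigma = 2.5$ natural-log
  units) rescaled exactly to the per-cell protein mass, spanning
  ~10²–10⁸ copies with a heavy top tail — under the defaults the 150
  most abundant of 5000 proteins hold 50–95% of all copies;
* the simulated histone set is pinned to the DNA mass (the nucleosome
  ~1:1 histone:DNA mass ratio), which is exactly the assumption that
  makes the proteomic ruler consistent with the total protein approach;
* intensities are copies × MW × sample scale × multiplicative
  log-normal noise (CV 0.1 by default); the per-sample scale factor
  defaults to CV 0, emulating upstream run-level normalisation;
* detection is Bernoulli with a logistic probability in log10 copies;
  the midpoint shifts with the input setting (3.7 at 1000 cells, 3.4 at
  4000, 2.8 at 100 000; steepness 2 per decade). The numbers are
  generator defaults chosen to reproduce the qualitative low-input
  behaviour — losses concentrate in low-abundance proteins and most of
  the bulk proteome survives — not measured dropout curves, which the
  underlying study does not provide;
* paired designs share a per-subject multiplicative offset across the
  two conditions (the pairing signal), and planted effects multiply
  condition-B copies by $2^{\mathrm{log_2FC}}$;
* titrations and bead tables are exact model evaluations with
  multiplicative noise.

Not emulated: peptide-level variation, interference/co-fragmentation,
intensity-dependent (rather than copy-dependent) missingness,
correlated noise across proteins, batch structure, or real ontologies.
Passing tests therefore demonstrate the correctness and numerical
behaviour of the estimators on data satisfying their assumptions — not
performance on any real dataset.

# Numerical choices and problem sizes

All randomness flows through explicit seeds; generators are pure
functions of (configuration, seed) and restore the caller's RNG state.
Saturation fits run with tight LM tolerances (ftol = ptol = 1e-15) and
bound $A, R_0 \le -10^{-12}$. The test and acceptance runs use sizes
chosen to make the statistical checks sharp while keeping the whole
suite in the minutes range on one CPU: 5000-protein proteomes for
composition statistics, 2000 proteins × 3 pairs for the null
calibration of the paired test (checked against the full $2^3$
sign-flip permutation oracle at 99% binomial bounds), 100 repetitions
for power and noise-recovery medians, 1000 random parameter sets for
the closed-form/bisection equivalence.

# Known limitations

Copy estimates inherit any departure from the intensity∝mass
assumption (ionisation efficiency, peptide count effects); the ruler
depends on complete histone detection and the histone:DNA assumption;
absolute levels scale with the configured per-cell masses. The paired
test is an ordinary t-test — no variance moderation — so power at
n = 3 pairs relies on the planted effects being large, as in the
benchmark (|log2FC| = 2 at CV 0.1). The enrichment stand-in does not
replicate proprietary scoring systems of web-based enrichment services;
results are comparable in kind, not in exact p-values.
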