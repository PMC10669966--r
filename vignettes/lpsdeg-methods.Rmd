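---
title: "Models and methods behind lpsdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lpsdeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpsdeg)
```

`lpsdeg` finds genes highly expressed in one liposarcoma subtype relative
to the other subtypes and to a broad tissue compendium, and provides the
downstream clinical statistics used to validate such candidates. This
vignette records the models, the parameter choices, and the reasoning
behind the design decisions that were genuinely open.

## The count model

Counts for gene $g$ in sample $s$ are modelled as negative binomial with
mean $\mu_{gs}$ and dispersion $\varphi$:

$$Y_{gs} \sim \mathrm{NB}(\mu_{gs}, \varphi), \qquad
\mathrm{Var}(Y_{gs}) = \mu_{gs} + \varphi\,\mu_{gs}^2 .$$

This is the standard overdispersed model for bulk RNA-seq gene counts;
$\varphi$ is the squared biological coefficient of variation. All
dispersion and testing machinery in the package is written against this
parameterization.

### Library-size equalization

The conditional exact test below requires equal sequencing depths.
`equalize_library_sizes()` rescales every sample's counts toward the
geometric mean library size, $y' = y \cdot \bar L / L_s$, rounding to the
nearest integer by default (a seeded stochastic rounding is available).
This is a mean-preserving approximation: per-gene adjusted means stay
within half a count of the exact rescaling, and equal input depths give
the identity. The geometric mean was chosen over the arithmetic mean
because depths are drawn from (and in practice distributed on) a
log scale.

No between-sample normalization factor is applied by default — the
analysis this package operationalizes works on raw library sizes. Because
a minority of very highly expressed genes can inflate a subtype's column
sums and bias all other genes downward (a composition effect), an
optional median-ratio correction (`normalize = "median_ratio"` in
`call_subtype_degs()`, `median_ratio_factors()`) re-estimates each
sample's depth as the median ratio to a geometric-mean reference gene
profile. It is off by default to match the primary analysis; the package
tests demonstrate both its benefit under strong planted effects and that
default calibration is nominal in the absence of composition stress.

### Dispersion estimation

The common dispersion maximizes the sum over genes of the NB *conditional*
log-likelihood given the per-group sums. For a group of $n$ i.i.d.
$\mathrm{NB}(\mu, \varphi)$ counts with $r = 1/\varphi$,

$$P(y_1,\dots,y_n \mid \textstyle\sum y_i = t) =
\frac{\prod_i \binom{y_i + r - 1}{y_i}}{\binom{t + nr - 1}{t}},$$

which is free of $\mu$, so no mean parameters need to be profiled out.
The maximizer is found by golden-section search on $\log\varphi$ over
$[10^{-6}, 10]$; data with no within-group variability drive the estimate
to the lower bound, and the estimate recovers a generative
$\varphi = 0.1$ within a few percent at 2000 genes × 60 samples.

Per-gene (tagwise) dispersions shrink each gene's own conditional
likelihood toward the common value by weighted likelihood:

$$\hat\varphi_g = \arg\max_\varphi \; \ell_g(\varphi) +
\frac{d_0}{2}\,\bar\ell(\varphi),$$

where $\bar\ell$ is the average conditional log-likelihood over all genes
(whose maximizer is the common estimate) and $d_0$ is `prior_df`
(default 10). $d_0 \to \infty$ returns the common value for every gene;
$d_0 = 0$ gives the raw per-gene estimates. $\bar\ell$ is evaluated on a
log-spaced grid densified around the common value and interpolated with a
natural spline, so the shrinkage target is located to well below the
reporting precision; each gene is then refined by golden-section search
in its bracketing grid interval. Shrinkage demonstrably reduces the mean
squared error of log-dispersion estimates when true dispersions vary
across genes.

### The exact test

For one subtype against the pooled rest, on equalized libraries, the
within-group sums are NB (a sum of $n$ i.i.d. $\mathrm{NB}(\mu,\varphi)$
variables is NB with mean $n\mu$ and size $n/\varphi$). Conditional on
the total $S = S_A + S_B$, the null distribution of $S_A$ is known up to
the common mean, estimated as $S / (n_A + n_B)$. The two-sided p-value
sums the probabilities of all splits whose probability does not exceed
the observed split's probability, with a relative tie tolerance of
$10^{-10}$ guarding floating-point comparisons:

$$p = \sum_{a : P(a) \le P(s_A)(1 + 10^{-10})} P(a), \qquad
P(a) \propto \mathrm{NB}_{n_A}(a)\,\mathrm{NB}_{n_B}(S - a).$$

The test is symmetric in the groups, depends on the data only through the
group sums, reduces to the conditional binomial test as
$\varphi \to 0$, and agrees with exhaustive enumeration to $10^{-10}$
(both properties are exercised in the test suite, the latter for every
split of every total up to 50).

### DEG calling

`call_subtype_degs()` tests every gene for each subtype against the
pooled remaining samples and calls a DEG when

* log2 fold change $> 1.5$ (group-mean CPM ratio with a depth-scaled
  prior offset, `prior_count = 2`, to stabilize low counts),
* raw $p < 0.05$, and
* the gene is not on the exclusion list.

These thresholds are the pipeline's published operating point and are the
package defaults. Raw p-values drive the call deliberately — the
reference analysis thresholds unadjusted p-values — and BH-adjusted
values are reported alongside for transparency. One-vs-rest is realized
as subtype versus pooled complement (not pairwise-minimum). Ranking is by
descending logFC, matching how such lists are usually presented. Whether
the logFC threshold should apply to a shrunken estimate instead of the
prior-damped CPM ratio is not determinable from the source analysis; the
documented formula above is used.

## The tissue-specificity exclusion list

From a compendium of per-sample expression values labelled by tissue and
by healthy/cancer category:

1. per-tissue, per-gene means over non-missing values, reported only when
   a gene has at least `min_datapoints = 6` values in that tissue
   ("datapoint" is read as a non-missing value for that gene in that
   tissue);
2. per-tissue top-`k` lists (`k = 500`), ties at the boundary broken by
   ascending gene identifier so results are platform-independent;
3. the exclusion list: genes appearing in at least one top list, at most
   `max_healthy = 1` healthy lists and at most `max_cancer = 3` cancer
   lists.

Membership of the union is required — a gene in no top list can never be
excluded, because the list is derived from the top lists. As written, the
rule excludes genes that top-rank in *few* other tissues and retains
ubiquitously high genes, which is arguably inverted relative to the goal
of removing non-specific genes; the rule is implemented verbatim, and the
complementary variant is available as `invert = TRUE` without any claim
that it reflects the original intent. Monotonicity properties (the list
never shrinks when caps are raised; membership counts never decrease with
`k`) are enforced by tests against a set-algebra oracle.

The licensed reference compendium itself (20,218 samples, 95 healthy and
106 cancerous tissue types) is not available; the synthetic generator
reproduces its structural features — per-tissue sample groups straddling
the 6-datapoint rule, housekeeping genes high everywhere, tissue-specific
genes high in designated tissues — with known ground truth. Its 2754-gene
output list is consequently not reproducible and is not a target.

## Expression QC

Log-CPM uses a depth-adjusted prior,
$\log_2\!\big((y + p_s) / (L_s + 2p_s) \cdot 10^6\big)$ with
$p_s = 2\,L_s/\bar L$, so zeros are finite and samples of equal depth and
counts map to equal values. The sample filter computes each sample's
median log-CPM over genes, the median $M$ of those medians, and excludes
samples with $|m_s - M|/|M| > 0.10$. Two readings were open: medians of
log-CPM versus raw log counts, and relative versus absolute deviation.
Log-CPM with relative deviation was chosen — depth normalization removes
library-size confounding, and a relative deviation is the only reading in
which a ">10%" rule is dimensionless; both are configurable. The gene
filter keeps genes with CPM of at least `min_count`/median-library-size
× 10⁶ in at least as many samples as the smallest subtype group and a
minimum total count, a documented simplification of the common
default-parameter filter; bit-compatibility with any external
implementation is not promised, and correctness is asserted against a
brute-force restatement of the rule.

## Clinical statistics

* **H-score**: staining intensity (0–3) × percent positive cells, in
  [0, 300]. Quartile classes use the printed closed ranges 0–75, 76–150,
  151–225, 226–300 — boundaries belong to the lower class — and the
  binary split is low ≤ 150. Fractional scores strictly between a
  boundary and the next integer fall in the upper class, the only
  consistent completion of integer-range bins.
* **Pearson χ²** is the uncorrected statistic: the uncorrected version
  reproduces the printed sex-association p-value (0.016) from the
  corresponding table, the Yates-corrected one does not.
* **Fisher–Freeman–Halton**: the exact r×c generalization of Fisher's
  test. All tables with the observed margins are enumerated recursively
  with margin bounds (the final free row vectorized), and the p-value
  sums multivariate hypergeometric probabilities not exceeding the
  observed one, with relative tie tolerance $10^{-7}$ — the convention of
  common statistical software. The enumeration's probabilities must sum
  to 1 (self-check returned to the caller); a seeded Monte-Carlo fallback
  (Patefield sampling) covers tables beyond the enumeration budget. On
  2×2 tables it reproduces the classical Fisher test exactly.
* **ΔΔCt**: triplicates are averaged (means, not medians — no efficiency
  correction is stated anywhere, so none is applied), and relative
  expression is $2^{-(\Delta Ct - \Delta Ct_{cal})}$ with
  $\Delta Ct = \overline{Ct}_{target} - \overline{Ct}_{reference}$.
* **Viability**: wells are background-subtracted by the mean medium
  signal, scaled by the mean background-subtracted control to percent;
  treatments are compared with the control by a two-tailed unpaired
  t-test, pooled-variance by default (the classical reading of "unpaired
  t-test") with Welch available by flag. Degenerate zero-variance plates
  are handled limit-consistently (p = 1 for equal means, p = 0
  otherwise) so zero-noise round-trips work.
* Mann–Whitney (exact for small untied samples, tie-corrected normal
  approximation otherwise), Kruskal–Wallis (tie-corrected, χ² reference,
  pairwise Mann–Whitney p-values multiplied by the number of pairs and
  capped at 1), and Spearman/Pearson correlations (t transform for the
  p-value; Spearman is Pearson on mid-ranks) are thin, validated surfaces
  over base R's implementations.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their specification and seed.
Defaults are fixed at the study conditions the pipeline targets:

* subtype design 53/54/24 (DDLPS/MLPS/PLPS), dispersion $\varphi = 0.1$
  (a typical bulk RNA-seq biological CV² for clinical tissue),
* baseline log2 means uniform on (0, 6) at a depth of $10^6$ — the
  moderate-depth regime of 3' tag counting, which also keeps exact-test
  enumeration totals tractable,
* library sizes log-uniform on $(5 \times 10^5, 2 \times 10^6)$,
  exercising the CPM normalization paths,
* compendium: 95 healthy + 106 cancer tissues, 3–12 samples per tissue
  (straddling the 6-datapoint rule), continuous log-scale expression
  scores (the exclusion-list algorithm needs only means and ranks, not
  counts), high genes separated from background by construction so
  top-list membership is guaranteed,
* IHC tables draw H-scores from truncated normals per subtype and derive
  intensity/percent backwards; sex and metastasis are independent of the
  score, making null-association checks exact by construction,
* qPCR and viability generators are built so zero noise recovers the
  planted truth exactly, anchoring round-trip tests.

Planted effects are clean multiplicative shifts on otherwise exchangeable
NB genes. Real FFPE RNA-seq additionally shows degradation gradients,
batch structure (carried as metadata but deliberately not modelled, as in
the primary analysis), gene–gene correlation, and GC/length biases. Tests
passing on these simulations therefore validate the statistical machinery
and the implementation, not robustness to those artefacts.

## Numerical choices

* All likelihood work is done in log space; the exact test normalizes
  with a log-sum-exp guard.
* Dispersion search interval $[10^{-6}, 10]$ on $\log\varphi$,
  convergence tolerance $10^{-8}$; tagwise grid: half-log2 steps over
  ±8 log2 units around the common value, with 0.05-step densification
  within ±0.5.
* Tie tolerances: $10^{-10}$ (exact test), $10^{-7}$ (FFH), chosen
  relative so they scale with the probability magnitudes.
* Deterministic tie-break (ascending gene id) wherever ranked lists are
  cut.
* Problem sizes in the test suite (up to 2000 genes × 120 samples,
  10 replicate seeds for recovery experiments, 100 random compendia for
  oracle equivalence) were chosen as the smallest sizes at which the
  statistical assertions have comfortable Monte-Carlo margins.

## Known limitations

* The exact-test path is the only DE framework; there is no GLM /
  quasi-likelihood route, no covariate adjustment, and no survival
  modelling.
* The gene filter is a stated simplification, not a re-implementation,
  of the common default filter.
* Enrichment is plain Fisher/BH; rank-corrected composite scores used by
  popular web services depend on their precomputed internals and are not
  reproducible, hence deliberately out of scope.
* With default settings the DEG caller inherits the composition
  sensitivity of raw-library-size analysis; the median-ratio option
  exists for users who need it.
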