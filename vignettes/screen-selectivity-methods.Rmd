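---
title: "Methods: differential drug-sensitivity meta-analysis and co-IP interactome scoring"
author: "screenselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential drug-sensitivity meta-analysis and co-IP interactome scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenselect)
```

# Scope

`screenselect` implements two statistical pipelines that are usually run on
public multi-screen drug-sensitivity releases (CTD2, GDSC1/2, PRISM-style
long tables) and on AP-MS protein-intensity matrices:

1. **Screen pipeline** — which compounds are selectively toxic to a target
   cell lineage (here: B-lymphoid lines vs a solid-tumour background)?
2. **Interactome pipeline** — which proteins are specifically enriched in a
   bait pulldown over its Ig control?

Both pipelines are deterministic given their inputs and a seed, and both are
exercised end-to-end on synthetic panels with planted ground truth, so the
entire artifact builds and tests without downloads.

# The screen pipeline

## Dose-response model

Every (screen, cell line, compound) series is fit with the four-parameter
log-logistic model

$$f(x) = c + \frac{d - c}{1 + \exp\{b(\ln x - \ln e)\}},$$

with slope $b > 0$ for curves decreasing in dose, lower and upper asymptotes
$c \le d$, and inflection $e$ — the relative EC50. `LL3_upper1` fixes
$d = 1$, the natural constraint when viability is normalised to an untreated
control; it is the mode used for EC50 reporting, since the free-$d$ model
trades asymptote against inflection on noisy 8-point series.

Fitting is bounded Levenberg-Marquardt (`minpack.lm::nls.lm`) on
$(b, c, d, \ln e)$ with bounds $b \in (0, 50]$, $c \in [-0.2, 1.2]$,
$d \in [0, 1.5]$, $e \in [d_{\min}/100,\; 100\,d_{\max}]$. Bounds prevent
degenerate optima (runaway slopes, inverted curves) while leaving room for
the slight over-/under-shoot real viability data show. Initialisation is
deterministic — $c_0 = \min y$, $d_0 = \max y$ (or 1), $e_0$ at the dose
whose response is nearest the midpoint — with a three-point multi-start over
$b_0 \in \{0.5, 1, 3\}$ keeping the lowest RSS, so fits are reproducible and
robust to the initial slope guess. We verified on simulated curves that this
multi-start attains the same optimum as a dense start-grid global search
(agreement to ~1e-6 in the recovered EC50).

A fit is declared *converged* only when the optimiser reports success, the
parameters are interior to their bounds, $c \le d$, and the dynamic range
$d - c$ exceeds 0.01. The last guard matters: on flat curves the inflection
is unidentifiable, so flat fits must not report an EC50 nor count as
effective.

`p_fit` is the extra-sum-of-squares F-test of the fitted model against the
constant-mean model on $(p_1 - 1,\; n - p_1)$ degrees of freedom. No
particular dose-effect test is canonical here; the nested F-test is the
standard choice. One caveat worth knowing: on truly flat curves the LL4
family is locally unidentifiable (with $c = d$, the slope and inflection
have no effect), so even the globally optimal fit absorbs fewer noise
degrees of freedom than the nominal numerator df assumes and the test
rejects *below* the nominal rate (about 2% at $\alpha = 0.05$ in our null
simulations, checked against a dense-start global optimiser to rule out
optimisation shortfall). The test is therefore conservative, never
anticonservative — the safe direction for a flag that feeds screen weights,
and the property the test suite asserts.

## AAC

The per-curve sensitivity summary is the area above the curve over the
tested window, normalised by the log-window width:

$$\mathrm{AAC} = 1 - \frac{1}{\ln d_{\max} - \ln d_{\min}}
  \int_{\ln d_{\min}}^{\ln d_{\max}} \mathrm{clamp}(\hat f,\, 0,\, 1)\; d\ln x,$$

evaluated by the trapezoid rule on a uniform 101-point log grid. The grid is
fine enough that refining to 1,001 points changes AAC by less than $10^{-4}$
for smooth fits. AAC is computed from the fitted curve, not the raw points,
and always from our own fits rather than portal-published AUCs, so screens
remain comparable under one convention. Non-converged fits keep the AAC of
their best-found parameters: a noisy but responsive curve still carries
sensitivity information even when its parameters sit on a bound.

## Differential selectivity and the effect size

Per screen and compound, target-lineage AAC values are compared to the
background panel with the Wilcoxon rank-sum test: mid-ranks for ties,
normal-approximation $z$ with tie-corrected variance and continuity
correction, and the signed effect size $r = z/\sqrt{n_1 + n_2}$, positive
when the target lineage is more sensitive. When the number of group
assignments is small (at most 20,000, e.g. both groups of size up to about
8) the two-sided p-value is computed exactly by enumerating the rank-sum
permutation distribution; the normal approximation takes over for larger
panels, where it is accurate. A minimum of 3 lines per group is required —
below that the effect size is meaningless — and compounds failing it are
skipped with a logged reason.

## EC-window weights and meta-analysis

A curve is *effective* when it converged, `p_fit < 0.05`, and the maximal
modelled inhibition over the window (1 minus the windowed minimum of the
clamped fit) strictly exceeds 50%. A screen's weight is the fraction of its
curves that are effective: a screen dosed far below the active range of a
compound class contributes mostly flat, non-significant curves and is
down-weighted.

Screens are combined per compound with

$$r_{\mathrm{comb}} = \frac{\sum_s w_s r_s}{\sum_s w_s}, \qquad
  z_{\mathrm{comb}} = \frac{\sum_s w_s z_s}{\sqrt{\sum_s w_s^2}},$$

a weighted mean for the single differential score and weighted Stouffer
combination for significance. The combiner behind "weighted meta-analysis"
is genuinely open; we chose this pair because it is the simplest one in
which (i) a zero-weight screen is exactly equivalent to omitting it, and
(ii) equal weights reduce to the unweighted Stouffer test. Both choices are
recorded in the run manifest. $z$ enters Stouffer directly (not re-derived
from $p$), which preserves sign information at $p \approx 1$. Random-effects
heterogeneity modelling is deliberately out of scope.

## Compound-set enrichment

Compounds are ranked by $r_{\mathrm{comb}}$; sets are all target-annotation
groups with **more than 5** member compounds in the ranked universe. The
statistic is the weighted Kolmogorov-Smirnov running sum of the preranked
convention (hit increments $\propto |s|^1$, miss decrements $1/(N - N_h)$,
ES the signed extremum). The null is compound-label permutation: size-matched
random member sets, not rank shuffles, which preserves the correlation
structure of the ranking. NES divides ES by the mean $|ES|$ of same-sign
permutations and $p_{\mathrm{perm}}$ uses the standard add-one estimator, so
$p > 0$ always; q is Benjamini-Hochberg across sets. With $n_{\mathrm{perm}}
= 1000$ the smallest attainable q is bounded by $\sim 10^{-3} \times$ the
number of sets — adequate for the planted-truth benchmarks; raise `n_perm`
for finer FDR resolution.

## Biomarker correlation

Per gene, expression is correlated (Pearson by default, Spearman by flag)
with a per-line sensitivity vector — the AAC of a chosen compound averaged
over screens. AAC is the default metric (EC50 is only defined for converged
sigmoidal fits and is window-censored); constant genes are reported with a
missing coefficient and excluded from the BH adjustment.

# The interactome pipeline

## Normalization and missingness

Samples are quantile-normalized on their *observed* values: each sample's
quantile function is linearly interpolated onto a common grid, the reference
is the cross-sample mean, tied values receive the mean of the quantiles they
span, and missing cells stay missing. Normalizing on observed values only is
the right order here because detection is intensity-dependent: imputing
first would distort the quantiles being equalised.

Missing cells are classified per (protein, condition): **MNAR** when the
protein was detected in fewer than two replicates of that condition
(detection in 0 or 1 replicate is evidence the protein sits near or below
the detection limit there), **MAR** otherwise. "Detected" means non-missing
after normalization; no intensity threshold is applied. Two is not "fewer
than two": a protein seen in exactly 2 of 4 replicates has MAR missing
cells.

## Mixed imputation

MNAR cells are imputed by MinProb: draws from a Gaussian centred at the
sample's 1% observed quantile with SD equal to 0.3 times the sample's
observed SD. These defaults mirror common left-censored imputation practice
and are configuration keys (`minprob_q`, `minprob_scale`).

MAR cells are imputed by maximum likelihood under a joint Gaussian across
samples, proteins acting as observations: EM with missingness-pattern
grouping, the conditional-covariance correction in the M-step, a $10^{-8}$
ridge on the observed-block solve, convergence when the largest parameter
change drops below $10^{-6}$ (100 iterations maximum, warning and best
iterate otherwise). Cells are filled with conditional expectations — no
posterior draws — so MAR imputation is deterministic; only the MinProb draws
consume randomness, under the user seed. The moderated test runs on the
imputed-complete matrix; this is recorded in the manifest
(`test_values = "imputed_complete"`).

## Moderated testing and contaminant downweighting

The two-group empirical-Bayes test: per-protein pooled variance $s^2_g$ on
$d_g$ df; hyperparameters $(d_0, s_0^2)$ by moment matching on $\log s^2_g$
(digamma/trigamma relations, Newton trigamma inversion to $10^{-8}$);
posterior variance $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$;
$t_{\mathrm{mod}} = \hat\beta_g / \sqrt{\tilde s^2_g (1/n_1 + 1/n_2)}$ on
$d_0 + d_g$ df; BH q-values. The implementation is validated in the test
suite against both a direct closed-form recomputation (to $10^{-8}$) and the
reference limma fit (to $10^{-6}$), and its null type-I error at $p < 0.05$
is inside $[0.04, 0.06]$ on a 3,000-protein 4-vs-4 Gaussian simulation.

For display, the bait-over-Ig fold change is divided by the protein's
average background binding from a CRAPome-style table, floored at 1 so that
proteins with near-zero recorded background (or absent from the table) are
not inflated — absent proteins keep their fold change unchanged.

# The synthetic-data generators

`simulate_screens()` emulates the statistical structure of public
multi-screen panels: per-screen log-spaced dose windows of different width
and placement, per-compound LL4 curves with slopes $b \sim U(0.75, 2.5)$ and
residual viability $c \sim U(0, 0.15)$, log-normal EC50s (meanlog 0, sdlog 1,
micromolar — centred near 1 uM as typical potencies are), Gaussian viability
noise (SD 0.05, the scale of replicate scatter in public screens), viability
clamped to $[-0.2, 1.5]$ to exercise the AAC clamping path, 5% of assays
dropped whole, and 15% of compounds made ineffective by placing their EC50
at $10^3 \times$ the maximal tested dose. The planted class divides its EC50
by `planted_shift` (default 50) in every target-lineage line — exactly, so
ground-truth ratios are checkable without tolerance. Defaults (3 screens,
120 compounds, 10 planted, 15 target vs 40 background lines) are the
benchmark conditions used throughout the tests and the acceptance script.
One RNG stream is drawn in a fixed order (curves, noise, missingness), so a
seed pins the panel byte-for-byte.

`simulate_interactome()` draws protein abundances $\mu_p \sim N(25, 2^2)$
(log2 scale), replicate noise with SD `rep_sd = 0.5` — the field's typical
replicate CV — and shifts `n_interactors = 50` proteins by `effect_delta = 2`
log2 units in bait samples. The replicate-noise layer is what gives the
matrix protein-level structure and hence the inter-sample correlation the
MAR imputation model exploits; without it, cells would be independent and
maximum-likelihood imputation would have nothing to borrow. Detection is a
logistic function of the true intensity (midpoint 21, slope 0.8), producing
roughly 10% missingness concentrated in the left tail — left-censoring by
construction.

What the generators do *not* emulate: between-screen batch effects beyond
dose-window differences, pharmacological mechanism (curve parameters are
drawn, not derived), correlated compound classes other than the planted
one, peptide-level effects, shared-peptide protein inference, or
interactor-abundance correlations. Passing the planted-truth benchmarks
therefore shows the statistics recover a known signal under the assumed
noise model — not that the pipelines are robust to every artefact of real
releases.

# Problem sizes and numerical choices

The benchmark problem sizes are the study conditions stated above: the
planted-class benchmark fits $3 \times 120 \times 55 \approx 20{,}000$
curves per seed and repeats over 10 seeds with 1,000 enrichment
permutations; the interactome benchmark runs the full pipeline on
$2{,}000 \times 8$ matrices over 10 seeds; EC50 recovery uses 200 curves on
8-point grids. Ties in ranking are mid-ranked everywhere; the enrichment
extremum takes the first position at which `which.max` attains the maximal
|running sum|; degenerate inputs (flat curves, constant genes, all-tied
groups, empty sets) are defined to return the conservative value (no
effect, missing, or a skip with reason) rather than erroring mid-pipeline.

# Known limitations

- The EC50 of a compound whose inflection lies far outside a screen's
  window is not estimable; such fits are flagged non-converged and excluded
  from EC-window weights, which is precisely what the weighting is for.
- Median relative EC50 error on noisy 8-point curves is ~9-10% — at the
  statistical information limit of that design (verified against a global
  optimiser); shallow slopes dominate the error.
- The MAR imputation assumes joint Gaussianity across samples; heavy-tailed
  intensity distributions would call for a robust extension.
- Permutation FDR resolution is capped by `n_perm`; there is no adaptive
  refinement.
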