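---
title: "Regression models of chromatin insulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression models of chromatin insulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulatr)
```

## The problem

Hi-C experiments measure, for every pair of genomic bins, how often the two
loci touch in the nucleus. Contact frequency decays with genomic distance
(the polymer effect), and on top of that decay the genome is organised into
topologically associating domains (TADs): contiguous regions whose internal
contacts are elevated relative to contacts that cross a domain border.
`insulatr` models border structure by regression. The key idea is that a
border bin acts *multiplicatively* on every contact that spans it, so on the
log scale each bin contributes an additive insulation effect to the pairs it
separates.

Three models share this design:

* **SIM** (sparse insulation model) calls borders and facilitators on one
  matrix;
* **DIM** (differential insulation model) tests border-strength changes
  between two matrices via experiment-interaction terms;
* **PIM** (prediction insulation model) fits a Poisson log-linear model of
  the counts and predicts the contact map after a deletion or inversion.

## SIM: the sparse insulation model

For bin pairs $(i, j)$ with separation at most `max_gap` bins, the distance
effect is removed first with a negative-binomial generalized additive model,

$$\log \mathrm{E}[y \mid d] = \beta_0 + f(d),$$

where $d$ is log bp separation and $f$ a cubic regression spline. Residuals
are formed on the log scale, $z = \log(y + c) - \hat\beta_0 - \hat f(d)$,
with pseudocount $c = 1$ for raw counts and half the smallest positive value
for balanced (non-integer) data. On this scale an insulation coefficient is
an additive effect on log contacts, the same role it plays in the prediction
model, so one set of coefficients serves all three models.

The residuals are then regressed on per-bin spanning indicators: the design
has one column per candidate bin, and entry 1 exactly when the bin lies
strictly between the pair. Sparsity comes from an L0 (best-subset) penalty,

$$\min_{\beta_0, \beta} \; \frac1N \sum_j \big(z_j - \beta_0 - X_j
\beta\big)^2 + \lambda \lVert \beta \rVert_0,$$

so unselected bins have exactly zero coefficients. Negative estimates are
borders, positive ones facilitators; border bins are tiered strong /
moderate / weak at $-2$ and $-1.2$.

### Numerical choices that matter

**Within-stratum centering.** The count-scale trend absorbs the *average*
insulation effect at each separation, so the residuals of non-spanning pairs
sit systematically above the trend by an amount that grows with separation —
and the indicator row sums equal `gap − 1`, so a diffuse uniform loading on
all bins could reproduce that offset and the selector would waste
coefficients on it. Both the residuals and the indicator columns are
therefore centered within each gap stratum before the sparse fit
(a Frisch–Waugh projection). Coefficients then estimate within-stratum
contrasts, which is the insulation signal proper. The log-scale Jensen
offset ($\mathrm{E}\log(y+c) \ne \log\mathrm{E}\,y$, largest at low counts)
is removed by the same centering.

**The L0 solver.** The objective is solved on the centered Gram scale by
coordinate descent with a local search over support moves — additions,
drops, and swaps, each scored by the exact penalized objective after a joint
OLS refit on the proposed support, using rank-one update identities so a
round costs little more than one matrix–vector product. For 12 or fewer
candidates the solver enumerates all supports exactly; the test suite checks
the iterative path against independent exhaustive enumeration. The path is
warm-started along 50 log-spaced $\lambda$ values from just above the empty
model downwards and terminates when the support exceeds 100 variables, as
best-subset path solvers do.

**Choosing $\lambda$.** Ten-fold cross-validation of the mean squared error,
with folds assigned by position modulo 10 after a seeded shuffle (default
seed 1789). The penalty is read off the curve with the one-standard-error
rule: the sparsest model whose CV error is within one SE of the minimum.
Minimizing a noisy CV curve over a fine grid selects spurious variables with
appreciable probability even on pure noise (model selection by CV-minimum is
not consistent); the 1-SE rule is the standard remedy and matches the
conservative behaviour a border caller should have — on decay-only synthetic
matrices the selected model is empty in essentially all runs, while every
planted border of the standard fixture is still recovered. `cv_rule = "min"`
is available for comparison.

**Prefiltering.** Best-subset search is applied directly up to 5000
candidate bins. Above that, a cross-validated lasso runs first and bins with
$|\hat\beta| > 0.2$ are kept. On planted-effect simulations the prefiltered
and direct pipelines select identical supports.

**Masked bins.** Zero-coverage rows are flagged and excluded from pairs and
candidates but never dropped, so bin ordinals stay aligned with genome
coordinates. Adjacent (gap-1) pairs carry no insulation information but
anchor the short-range end of the distance trend and are kept.

**Tie-breaking at adjacent bins.** Spanning indicators of adjacent bins are
nearly collinear, so one physical border occasionally splits across two
neighbouring bins. Per-bin coefficients are reported untouched; for
human-readable output, selected bins at most two apart with the same sign
are additionally merged into "border regions".

## DIM: differential borders

Each experiment gets its own distance trend, so sequencing-depth and decay
differences cannot masquerade as differential insulation; a global offset
between experiments is absorbed by the experiment main effect. The retained
bin set is the union of the two SIM supports, with runs of consecutive bins
collapsed to the bin with the larger maximum $|\hat\beta|$ (ties to the
lower ordinal) — adjacent-bin ambiguity between experiments would otherwise
split one border into two spurious differential calls. Stacked residuals are
fitted by OLS,

$$\mathrm{E}[z \mid S, e] = \beta_0 + S\beta_S + \beta_e e + \textstyle\sum_j
\beta_{s_j e}\, s_j e,$$

with $e \in \{0, 1\}$ the experiment indicator. No penalty is needed — the
bins were already selected — which keeps interaction estimates unbiased
(mean within $\pm 0.01$ of zero over null simulations). A negative
interaction means stronger insulation in the second experiment.

Because log-count residual variance is roughly $1/\mu$, variance is largest
exactly at the strongly insulated pairs of the bins being tested, and
classical OLS standard errors understate the uncertainty there: measured
type-I error was about five times nominal. Standard errors are therefore
heteroskedasticity-consistent (HC3 sandwich) by default, which restores the
nominal level (raw $p < 0.05$ fraction ≈ 0.06 under the null);
`se_type = "classical"` is available. P-values are Benjamini–Hochberg
adjusted across the retained bins; the procedure is the field's default
when a plain adjusted p-value is reported.

## PIM: predicting rearranged maps

The prediction model is a Poisson GLM with log link,

$$\log \mathrm{E}[y \mid d, X] = \beta_0 + \beta_d d + X \beta_X,$$

fitted without any sparsity penalty — sharp border identification is not
needed for prediction, and a dense coefficient profile captures graded
insulation (a restriction to SIM-selected bins is available for speed).
Bins that never span a pair (chromosome ends, masked bins) are
unidentifiable; their coefficients are fixed at zero and flagged. Should the
fit fail to converge, a tiny ridge penalty ($10^{-6}$) stabilises it;
non-integer (balanced) inputs are rounded with a warning and a quasi-Poisson
dispersion is reported as a diagnostic.

A rearrangement edits the model variables, not the model: for a deletion,
the separation of every surviving pair shrinks by the deleted length between
them and the deleted bins' indicator columns vanish; for an inversion, bins
flip in place and both variables are recomputed from the new ordering, each
bin carrying its trained coefficient with it. Operations compose left to
right, with later intervals interpreted on the already-rearranged genome.
The predicted map is $\exp(\hat\beta_0 + \hat\beta_d d' + X'\hat\beta_X)$
over all pairs within `max_gap` on the new bin table. With no rearrangement
this reproduces the training fitted means exactly, and applying the same
inversion twice is exactly the identity on $(d', X')$.

Agreement between maps is measured three ways: Pearson correlation of
$\log(x+1)$ counts, Spearman correlation of counts, and the
stratum-adjusted correlation (SCC) — per-separation Pearson correlations
combined with weights proportional to stratum size times the geometric mean
rank standard deviation, so the distance decay itself contributes nothing.
Strata where either map is constant are skipped; fewer than three usable
strata make the SCC undefined and it is flagged rather than forced. An
optional 2D mean filter (off by default, window 1 when enabled) can smooth
both maps first.

## The synthetic generator

All statistical claims in the test suite are established against a
generative model the package also exports: for bins $i < j$,

$$\log \mu_{ij} = \beta_0 - \alpha \log(\mathrm{dist}_{ij}) +
\textstyle\sum_{i<k<j} \beta_k,$$

with Poisson or negative-binomial counts around $\mu$. The decay is a pure
power law, so the spline trend must recover a known curve. The standard
fixture is 200 bins at 25 kb (a ~5 Mb region), about 100 counts at one-bin
separation, $\alpha = 1$, eight borders with strengths spanning $-2.5$ to
$-1.0$ and two facilitators ($+1.0$, $+1.5$), spaced so no two planted bins
fall within one ten-bin window — echoing a deep Hi-C map of a gene-dense
region where roughly ten borders of varying strength and one facilitating
region would be visible in 10 Mb. Differential simulations use 100 bins at
depth 400 (ultra-deep coverage, as differentiation studies use), three
borders, and a single border strengthened by $\Delta\beta = -1.5$ in the
second condition. Prediction-model checks pool 21 replicate matrices
(~20 000 pairs) so coefficient recovery is measured at realistic precision.

What the generator deliberately does *not* emulate: A/B compartments,
loop/dot anchors, nested TAD hierarchies, mappability biases, or
translocations. Passing tests therefore demonstrate correctness of the
estimators under the model's own assumptions — log-additive insulation on a
power-law background — not robustness to every feature of real maps. On real
data the balanced input should be used for SIM/DIM, and PIM expects raw-ish
counts.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `max_gap` | 10 bins | maximal pair separation entering the models; larger values see longer-range structure at quadratic cost |
| `spline_df` | 8 | basis dimension of the distance spline (capped below the number of distinct separations) |
| `nlambda` | 50 | size of the log-spaced L0 penalty grid |
| `cv_folds` / `cv_rule` | 10 / `"1se"` | cross-validation folds and read-off rule |
| `prefilter_threshold` / `prefilter_trigger` | 0.2 / 5000 | lasso prefilter cutoff and activation size |
| `strong` / `moderate` | −2.0 / −1.2 | border tier thresholds |
| `alpha` (DIM calls) | 0.05 | BH-adjusted significance cutoff |
| `seed` | 1789 | fold assignment and any other internal randomness |

## Known limitations

* Per-chromosome, cis-only: no trans contacts, no `.hic`/cooler binary
  containers (dense and triplet text formats are supported; ICE balancing is
  the only implemented normalization).
* Two conditions only in DIM; no replicate-aware variance modelling.
* Deletions and inversions only in PIM; duplications and translocations
  change the pair universe in ways the variable transforms do not cover.
* The residual definition (log scale with pseudocount) attenuates very
  strong effects at low counts; border calls are unaffected but
  $|\hat\beta|$ of a $\beta \le -2$ border at modest depth reads a few
  tenths low. Noiseless-data checks in the suite therefore use a zero
  pseudocount, which is exact when all counts are positive.
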