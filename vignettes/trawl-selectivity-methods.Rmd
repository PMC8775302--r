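---
title: "Estimating trawl gear size selectivity from covered-codend data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating trawl gear size selectivity from covered-codend data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trawlselect)
```

## The problem

Bottom-trawl fisheries regulate which fish sizes a gear retains through two
devices acting in sequence: a square mesh panel (SMP) in the extension piece,
through which small fish can escape before reaching the codend, and the
codend itself, whose meshes perform the final size selection. In a
covered-codend selectivity experiment a fine-mesh cover is mounted over the
codend — and, in the dual-cover variant, over the SMP as well — so that every
fish entering the gear is recovered in exactly one of three compartments:
the codend (CD), the codend cover (CC, codend escapees) or the panel cover
(PC, panel escapees). Counting fish per 1-cm length class and compartment
turns selectivity estimation into a binomial regression problem.

`trawlselect` implements the full inference chain for such experiments:
retention models, pooled maximum-likelihood fitting, double-bootstrap
uncertainty, pairwise gear comparison via delta curves arranged in treatment
trees, and exploitation-pattern indicators.

## Retention models

Codend retention follows the standard logistic selection curve,
parameterized by the length at 50% retention ($L50$) and the selection range
($SR = L75 - L25$):

$$ r_{CD}(l) = \frac{\exp(\ln 9 \,(l - L50)/SR)}{1 + \exp(\ln 9\,(l - L50)/SR)}. $$

Panel escape is behaviorally mediated: a fish escapes only if it actively
contacts the panel. The CLogit model mixes a length-independent contact
probability $C \in [0, 1]$ with logistic escape for the contacting fraction:

$$ r_{SMP}(l) = 1 - C + C \cdot \mathrm{logit}(l, L50_{SMP}, SR_{SMP}), $$

so retention is bounded below by $1 - C$: small fish that never contact the
panel are retained regardless of length. A whole gear retains a fish only if
both stages do, hence the combined curve is the product
$r_{comb}(l) = r_{SMP}(l) \times r_{CD}(l)$; a gear without a panel is the
$C = 0$ special case.

## Fitting

Counts are first raised by each haul and compartment's subsampling factor
$q$ (ratio of length-measured to total fish), then pooled over hauls. The
SMP likelihood contrasts fish that stayed in the gear (CD + CC) against
panel escapees (PC); the codend likelihood contrasts CD against CC. Both are
binomial negative log-likelihoods minimized over the model parameters
(`fit_smp()`, `fit_codend()`).

Numerical choices that matter:

* **Bounds.** $L50, SR \ge 0.1$ cm. Degenerate datasets (e.g. a panel no
  fish escapes through) push estimates onto this bound; clamping at 0.1
  inside the objective makes boundary fits land exactly on 0.10 and keeps
  them comparable across gears. $C$ is searched through a logistic
  transform, which respects $[0, 1]$ without hard clipping.
* **Multi-start.** CLogit likelihoods are multimodal in $C$ (a flat curve
  can be explained by small $C$ or by an $L50$ far outside the data), so
  fitting is a deterministic multi-start Nelder–Mead search: $L50$ at data
  quantiles, $SR \in \{1, 5, 10\}$ cm, $C \in \{0.1, 0.5, 0.9\}$ — 27 starts
  for the panel model, 12 for the codend. The test suite verifies the
  optimum against exhaustive grid search at 0.01 resolution on small
  datasets.
* **Zero counts** contribute zero to the likelihood
  ($0 \cdot \ln 0 \equiv 0$); a retention of exactly 1 where escapees were
  observed yields $+\infty$, steering the optimizer away rather than
  erroring.
* **Binning.** Length classes are 1 cm wide and labelled by their lower
  bound (fish are measured to the nearest centimetre below). Curves applied
  to binned data are evaluated at class midpoints (label + 0.5) by default,
  which minimizes binning bias; lower-bound evaluation is available via the
  `at` argument, since published figures do not always state the convention.
* **Degenerate data.** Empty datasets error. Datasets where one outcome
  group is empty at every length (e.g. everything retained) are fitted to
  the boundary and flagged `boundary = TRUE` rather than rejected, so
  screening large batches of gears does not stop on an uninformative one.

Goodness of fit is summarized by the deviance against its degrees of freedom
and the chi-square upper-tail p-value (`model_diagnostics()`,
`gof_p_value()`). A cell is a (haul, length class) pair with nonzero raised
total; a pooled per-length-class convention is available, because published
degrees of freedom cannot generally be re-derived without the raw haul
structure. When the p-value is small and the deviance far exceeds the
degrees of freedom, `deviance_residuals()` supports inspecting whether the
misfit is structural or over-dispersion. Whether published deviances were
computed on raised or measured counts is typically unstated; raised counts
are used here, consistent with the likelihood.

The smallest length classes can escape through the cover meshes themselves,
which would bias the curves; `apply_length_filters()` therefore removes PC
counts at classes ≤ 20 cm and CC counts at classes ≤ 15 cm by default
(both configurable).

## Double bootstrap

Selectivity data have two variance layers: fish-level sampling within a haul
and haul-to-haul variation in gear performance. `double_bootstrap()`
resamples accordingly: hauls with replacement (outer), then, within each
selected haul, the measured fish of each compartment multinomially over
length classes, preserving the compartment's measured total (inner).
Resampling operates on measured counts and re-applies $q$ afterwards,
because measurement subsampling is the within-haul observation process while
$q$ is a known raising constant, not a random outcome. Each repetition is
refitted (warm-started from the point estimate; the tests confirm
warm-started and full multi-start refits give identical intervals). Failed
refits are redrawn rather than dropped so the ensemble keeps exactly `B`
entries in a fixed order; more than 20% failures aborts. The default
`B = 1000` matches field practice; the test suite uses `B = 200` for
desk-scale runtime.

Intervals are Efron percentile intervals. The finite-sample percentile rule
is left open by the percentile method itself; this package uses empirical
quantiles with linear interpolation between order statistics (R's type 7),
applied pointwise for curve bands (`curve_band()`) and to scalar parameter
collections (`efron_ci()`).

## Comparing gears: delta curves and treatment trees

The delta curve $\Delta r(l) = r_{treatment}(l) - r_{baseline}(l)$
quantifies where two gears select differently. Its confidence band comes
from per-repetition differences, pairing the two ensembles by bootstrap
index — valid because the two resamplings are independent — and a length
class is significantly different where the band excludes zero
(`delta_curve()`). Combined-gear ensembles (`combine_ensembles()`) inherit
the index pairing, so whole-gear comparisons work the same way.

With ten candidate designs (four SMP variants plus no panel, times two
codend geometries), pairwise comparison is only readable if organized.
`build_treatment_tree()` arranges the designs as a tree rooted at the
reference design (the commercially used `SMP_TS+CD_D`): an edge connects a
baseline to a treatment when they differ by exactly one atomic modification
— change SMP size, change SMP position, remove/add the SMP, or change
codend geometry — and the treatment is one breadth-first step farther from
the reference. SMP presence, size and position are treated as independent
axes, with removal counting as a single modification whatever the removed
panel's geometry. Pairs at equal distance from the reference (e.g.
`SMP_BS+CD_D` and `CD_D`, both one step away) are not edges: neither is a
step *forward*. The edge set is exported (`write_treatment_tree()`) for
inspection, and `render_tree()` draws delta, selectivity or catch-profile
panels per edge/node.

## Catch patterns and indicators

In a dual-cover experiment the entering population is fully observed
(`estimate_entering_population()`: raised CD + CC + PC). Applying a combined
curve gives the retained population $nr_l = nPop_l \cdot r_{comb}(l)$
(`retained_population()`) and three indicators
(`exploitation_indicators()`) relative to the minimum conservation
reference size (MCRS; hake 27 cm, blue whiting's 18 cm marketable-size
proxy):

$$ nP^- = 100\frac{\sum_{l < MCRS} r_{comb}(l)\, nPop_l}{\sum_{l<MCRS} nPop_l},\quad
   nP^+ = 100\frac{\sum_{l \ge MCRS} r_{comb}(l)\, nPop_l}{\sum_{l \ge MCRS} nPop_l},\quad
   nDiscard = 100\frac{\sum_{l < MCRS} r_{comb}(l)\, nPop_l}{\sum_{l} r_{comb}(l)\, nPop_l}. $$

A class labelled 27 spans [27, 28) cm and counts as at-or-above an MCRS of
27, consistent with nearest-centimetre-below measurement. Indicator
uncertainty recomputes the three ratios per bootstrap repetition, pairing
the curve ensemble with a population ensemble by index
(`indicator_cis()`); the joint-resampling convention is a documented choice,
as published analyses do not fully specify how curve and population
uncertainty combine. The traffic-light mapping (`traffic_light()`)
interpolates linearly in RGB from green (best) through yellow at the
midpoint to red (worst), with the orientation set per indicator; the
green/yellow/red category split at badness thirds and the anchor points are
conventions, configurable in principle, as only a "gradual" gradient is
standard.

## The synthetic-data generator

Because raw haul data from selectivity cruises are rarely deposited, the
package ships a generator (`simulate_dataset()`) producing data with exactly
the structure the analysis assumes: a mixture-of-normals length population
discretized to 1-cm classes; per fish, independent Bernoulli fates through
the sequential gear (escape through the panel with probability
$1 - r_{SMP}$, then codend retention with probability $r_{CD}$); binomial
thinning of each compartment at its subsampling rate; and haul-level
heterogeneity as a log-normal multiplicative perturbation of the $L50$s —
the simplest structure that makes the between-haul bootstrap component
consequential.

Defaults represent a mid-scale cruise: bimodal population (modes 22 and
35 cm), 10 hauls of 500 fish, 5% CV on haul-level $L50$s, full measurement.
The acceptance suite runs parameter recovery at exactly these sizes — 100
simulated cruises, `B = 200` bootstrap repetitions — and the grid-search,
law-of-large-numbers and coverage checks use datasets from hundreds to
$10^5$ fish; these problem sizes are the package's chosen desk-scale
experiment design.

What the generator does **not** emulate: behavioural length-dependence of
contact (C is length-free by model assumption), towing-condition
covariates, species mixtures within a haul, cover-mesh escape (the
motivation for the length filters), and over-dispersion beyond binomial.
Passing recovery tests therefore demonstrate correctness of the inference
machinery under the model's own assumptions, not robustness to real-data
violations of them.

## A known property: pooled estimation under haul heterogeneity

One coverage result deserves emphasis. With 5% CV between-haul variation on
$L50$, the pooled-likelihood estimand is *not* the per-haul component
truth: averaging logistic curves whose $L50$ varies flattens the average
curve, so the pooled $SR$ converges to a slightly larger value (for the
default codend truth $SR = 4$, to about 4.29). The double-bootstrap
intervals are calibrated for the pooled estimand (~93–95% empirical
coverage), but for tightly-estimated parameters the bias is comparable to
the interval width: empirical coverage of the component truth over 100
synthetic cruises is about 96% ($C$), 99% ($L50_{SMP}$), 98% ($SR_{SMP}$),
88% ($L50_{CD}$) and 85% ($SR_{CD}$). The corresponding acceptance test
asserts the nominal band for every parameter and is expected to fail for
$SR_{CD}$: the failure documents a real property of pooled estimation under
between-haul heterogeneity, not an implementation defect. Users comparing
pooled estimates to per-haul mechanism parameters should expect upward $SR$
bias whenever hauls are heterogeneous; a random-effects (Fryer-type)
between-haul model, which would remove it, is out of scope.

## Limitations

* Covered-codend designs only: no paired-gear or catch-comparison
  estimation.
* No over-dispersion correction factor; residual inspection is supported
  but no REP-style variance inflation is applied.
* Symmetric logistic curves only (no Richards asymmetry); dual selection is
  limited to the sequential product model.
* Percentile intervals only (no BCa/studentized), and modest undercoverage
  is expected with few hauls, as is generic for haul-level resampling.
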