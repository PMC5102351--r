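---
title: "Modeling introgression thresholds on stream networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling introgression thresholds on stream networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamhyb)
```

## The model

`streamhyb` treats hybridization between introduced rainbow trout and native
westslope cutthroat trout as a threshold-exceedance problem. A genotyped
site yields PRTA, the percentage of rainbow-trout alleles among all scored
alleles, and the management-relevant question is whether PRTA exceeds 1%,
10% or 20%. For each threshold $t$ the package fits

$$\operatorname{logit} P(\text{PRTA} > t \mid x) = \beta_0 + \beta^\top x,$$

where $x$ collects reach-scale habitat and zoogeographic covariates: mean
August stream temperature (`t_aug_c`, °C), reach slope (`slope_pct`),
flow-regime descriptors (`maf_cms`, `w95_days`, `cfm_day`), projected
coordinates (`easting_m`, `northing_m`), the historical rainbow-trout range
indicator (`rt_range`), Yellowstone-cutthroat introgression (`ycti`), and
three along-network propagule-proximity distances (`df3_m`, `dt13_m`,
`ds_m`). The underlying ecological claim is that introgression is governed
by temperature-mediated habitat overlap and by propagule pressure that
decays with along-channel distance from rainbow-trout sources.

Key modeling assumptions: sites are treated as independent (no spatial
autocorrelation term), effects are additive on the logit scale with no
interactions, and the three thresholds are modeled marginally rather than
as an ordinal response. These match standard practice for riverscape
hybridization assessments; the consensus rule below is what ties the three
fits together.

## The network and its covariates

A stream network is a tibble of reaches, each with one downstream pointer,
so the topology is a forest and junctions are implicit. Before modeling,
marginal habitat is trimmed: intermittent reaches, summer flows below
0.028 m³/s (mean annual flow stands in for summer flow unless a dedicated
column is prepared upstream of the package), mean annual flows above
5.66 m³/s (rivers too large to be cutthroat spawning habitat), and reaches
steeper than 10% *together with everything upstream of them* — steep reaches
typically sit below natural barriers, so the rule trims the network from its
upper extent. Rules are applied to the original attributes in a fixed order
(intermittent, low flow, high flow, slope propagation) so removals do not
cascade into each other, and every removal is logged with its reason.

Distances are along-channel, midpoint to midpoint, on a junction graph:
every reach contributes two half-length edges joined at a midpoint vertex,
so a parent and child reach are $(L_1+L_2)/2$ apart and so are two
tributaries meeting at a junction. This replaces the 30-m raster tracing of
GIS implementations with exact vector arithmetic; a `quantize_30m` flag
rounds results to 30-m multiples for fidelity comparisons. Three design
choices matter:

- **Traversal through trimmed water.** By default distances are computed on
  the *untrimmed* network (`use_untrimmed = TRUE`): fish and their
  propagules move through main stems that the trimming rules exclude from
  the hybrid-zone network itself — indeed the source-distance definition
  references reaches (flow ≥ 2.83 m³/s) that can exceed the 5.66 m³/s trim
  cap. The flag exposes both behaviors.
- **Unreachable targets** yield an explicit `NA`, never a large sentinel
  number; sites with missing distances are excluded from fitting with a
  logged count.
- The source distance `ds_m` takes the minimum over warm reaches, big
  reaches and flagged sources, so `ds_m <= min(df3_m, dt13_m)` always — a
  property the tests assert.

Trimming happens before sites are attached; a site landing on a trimmed
reach is reported as an error rather than silently dropped, because it
usually indicates a network/site mismatch the analyst should see.

## Estimation and model selection

The logistic fits use iteratively reweighted least squares written in the
package (deviance-change tolerance $10^{-8}$, 100-iteration cap).
Covariates are standardized internally — easting is of order $10^6$ m while
distance effects are of order $10^{-4}$ per m — and estimates, standard
errors and the covariance are back-transformed so reports are in raw units.
Complete separation is flagged by a guard at $|\beta| > 15$ on the
standardized logit scale (a per-SD odds ratio above $e^{15}$ is not a
finite estimate in any meaningful sense); guarded fits are retained in
rankings but marked non-converged. Standard errors come from the inverse
Fisher information and p-values from the normal approximation to $z$,
matching how such tables are published.

Covariate screening removes, for each pair with $|r| \ge 0.8$, the member
whose single-covariate model has the higher AIC (ties retain the
alphabetically earlier name), then reports variance inflation factors with
a flag at 3.5. Subset selection is *exhaustive*: every one of the $2^k$
subsets is fitted (capped at $k = 12$), ranked by AIC with ties broken by
parsimony and then lexicographically. Exhaustive enumeration was chosen
over stochastic searches (genetic algorithms and the like) because at this
candidate-set size determinism and oracle-testability cost nothing.

The consensus rule picks the covariate subset that is top-ranked at both
the 10% and 20% thresholds, provided its AIC at the 1% threshold is within
3 points of that ranking's best; the subset is then refitted per threshold
so coefficients stay threshold-specific. Two edge cases the rule itself
does not define: if the shared top fails the 1% window the package returns
an explicit no-consensus result (the pipeline then carries per-threshold
top models and says so); if the 10% and 20% tops disagree, a labelled
extension picks the subset minimizing summed AIC rank subject to the
3-point window at every threshold. For the fish-level metric PFRT, where
practice selects a best model per threshold instead of a consensus,
`per_threshold_best = TRUE` skips the rule.

## Evaluation

AUC is the Mann–Whitney probability that a random exceeding site outscores
a random non-exceeding site, ties counting one half. The classification
cutoff scans all candidate values (unique scores plus 0 and 1, predicting
positive at or above the cutoff — the tie goes to "positive" everywhere
outputs appear) and minimizes $|FN - FP|$, breaking ties toward the
smallest cutoff; this equalizes omission and commission errors rather than
maximizing raw accuracy, appropriate when both error types carry management
cost. Cross-validation uses a seeded uniform random partition into k
near-equal folds (stratified assignment available behind a flag), assigned
in a canonical row order so the partition is invariant to row order. The
balanced cutoff is recomputed inside each training set — the conservative,
leakage-free choice — and held-out accuracy is pooled over folds. Folds
whose training data collapse to one class are flagged and excluded, not
fatal.

## Scenarios and habitat accounting

Six standard projections combine stream warming (+0, +0.5, +1.0 °C applied
to every reach) with an equilibrium assumption (introgression outside the
historical rainbow-trout range rising to inside-range levels, encoded by
setting `rt_range = 1` everywhere — the range indicator is the model's only
inside/outside distinction). Warming recomputes the warm-habitat distances
`dt13_m` and `ds_m` by default, because newly warm reaches become
springboards for propagules; `recompute_distances = FALSE` isolates the
direct temperature effect for sensitivity analysis. With the expected
coefficient signs (warmer +, inside range +, farther from sources −), the
below-threshold habitat sets are nested across warming — an invariant the
tests assert on the synthetic network.

Habitat below a threshold is summed by length and by volume, stratified by
the *current* range indicator so equilibrium rows stay comparable. No
volume definition is standard in this literature, so the package states
its own: volume = length × width × depth with downstream hydraulic-geometry
power laws, width $= a\,\mathrm{MAF}^{b}$ and depth $= c\,\mathrm{MAF}^{f}$,
defaults $a = 4.3, b = 0.5, c = 0.27, f = 0.4$ (classic downstream
exponents; all four configurable, and the formula is recorded in the
output's metadata). Percent changes are reported to one decimal, lengths
in km.

## The synthetic riverscape

Because the motivating field datasets (hundreds of genotyped sites on a
multi-state hydrography network) are not redistributable, the package ships
a two-tier simulator whose defaults emulate that study system.

The **network generator** grows a random bifurcating tree from an outlet;
mean annual flow accumulates downstream (children's flow plus a lateral
lognormal increment, so conservation holds by construction), temperature
follows $T = 12.3 + 1.1\ln(\mathrm{MAF}) + \mathcal N(0, 0.7)$ °C floored
at 4 °C, slope decreases downstream as $4.2\,(\mathrm{MAF}/0.3)^{-0.3}$
with lognormal noise, winter-high-flow days and flow-mass timing are
strongly anticorrelated ($\mathrm{CFM} = 228 - 9\,\mathrm{W95} + \mathcal
N(0,5)$), and a contiguous historical range covering ~40% of reaches is
assigned by subtree. Reach lengths are lognormal with median 2.4 km, chosen
so the site-level source-distance medians land in the published
site-statistics envelope (roughly 4–8 km) rather than the few-hundred-meter
artifacts a very short-reach, desk-scale basin would produce. With 400
reaches the covariate medians (T ≈ 10.6 °C, MAF ≈ 0.2–0.3 m³/s, slope ≈
4–5%) sit inside that envelope too; the tests check this.

The **genotype simulator** draws a latent site admixture
$A = \operatorname{logit}^{-1}(\beta^\top x + \varepsilon)$, with $\beta$
defaulting to published consensus estimates for the 10% threshold and
$\varepsilon \sim \mathcal N(0, 0.8)$. Each of $n \approx 24$ fish is
nonadmixed with probability $q(A) = (1-A)^2$ — admixed populations retain
many nonadmixed individuals — and otherwise has Beta-distributed ancestry
with mean $1/(2-A)$, so the site's expected ancestry is exactly $A$; each
fish is scored at 20 codominant diagnostic markers, two alleles each,
binomially in its ancestry. PRTA ≤ PFRT then holds at every site by the
allele-count identity, the two metrics are highly correlated (r ≈ 0.9 at
defaults), and threshold exceedances are nested because all three derive
from the one latent $A$. Markers are fully diagnostic by default; a
`genotyping_error_rate` knob exists because real assay error can exceed 1%.
The second tier, `simulate_bernoulli_outcomes()`, draws outcomes exactly
from the fitting likelihood and exists to separate estimator correctness
from model misspecification: the genotype tier's exceedance data follow the
logistic model only approximately, which is precisely what makes it a
useful end-to-end stress test.

What passing tests on this synthetic system do *not* show: real riverscapes
have barriers, non-random sampling designs, spatially autocorrelated
residuals and genotyping error, none of which the generator emulates.
Results on synthetic data demonstrate that the machinery is correct, not
that any particular field system satisfies the model.

## Numerical choices and degenerate inputs

- Problem sizes are chosen for a desk-scale run: the shipped configuration
  uses a 400-reach network, 500 sites, exhaustive selection over the
  post-screen candidate set, and 100-replicate recovery experiments at
  n = 5000; the full pipeline completes in well under a minute.
- AIC ties break by parameter count then covariate names, so rankings are
  total orders and byte-reproducible.
- `percent_change` returns an explicit `NA` marker when the current amount
  is zero, and the current scenario's change columns are `NA` by
  definition (the "—" cells of published habitat tables).
- Single-class outcomes, rank-deficient designs, unknown covariates, sites
  on removed reaches and cycles in the topology all raise typed errors
  naming the offending column, site or reach.
- All randomness flows from explicit seeds; generator and simulator
  restore the caller's RNG state.

## The interface

The package is tidyverse-shaped: every user-facing function takes a data
frame first and returns a tibble, fitted models have `tidy()`/`glance()`
methods, and result types have `autoplot()` methods. The pipeline is a set
of composable stages — `load_network()`/`generate_network()`,
`trim_network()`, `attach_site_covariates()`, `collinearity_screen()`,
`all_subsets_selection()`, `select_consensus()`, `evaluate_model()`,
`run_scenarios()` — orchestrated by `run_pipeline()`, which writes every
artifact (model tables, rankings, evaluation report, per-reach
classification, habitat table, run log with config hash and seed) as
delimited text and JSON. These functions, plus `scripts/acceptance.R`, are
the package's command surface; no separate shell executable is provided
because the intended users work in R.

## Known limitations

Barriers to fish movement are not modeled (distances assume passable
channels); coefficient uncertainty is not propagated into scenario maps
(no simulation from the coefficient covariance); interactions and spatial
random effects are out of scope; and the volume accounting is only as good
as its hydraulic-geometry constants, which should be re-calibrated for
basins unlike mid-latitude montane streams.
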