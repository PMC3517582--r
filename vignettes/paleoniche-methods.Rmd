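---
title: "Phyloclimatic modelling with paleoniche: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phyloclimatic modelling with paleoniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoniche)
```

## The problem

Where could the ancestors of a clade have lived?  For a group such as the
ivesioid cinquefoils (*Ivesia*, *Horkelia*, *Horkeliella*; Rosaceae) of
western North America — drought-adapted herbs whose sister lineage prefers
moist habitats — the question is whether the clade diversified in response
to regional aridification.  paleoniche implements the phyloclimatic
modelling workflow used to address it: climate envelopes of living species
are treated as heritable continuous characters, reconstructed at the
internal nodes of a dated phylogeny, and projected into paleoclimate grids
to map where the inferred ancestral climate existed at the time of each
node.

## The envelope model

A taxon's bioclimatic envelope is, per climate variable $v$, the closed
interval $[\min_v, \max_v]$ of values observed at its occurrence
localities.  Projecting an envelope into a gridded scenario scores each
cell by

$$s(\text{cell}) = \frac{\#\{v : \min_v \le x_v(\text{cell}) \le \max_v\}}{L},$$

the fraction of the $L$ modelled variables whose cell value falls inside
the interval, so $s \in \{0, 1/L, \dots, 1\}$.  Maps distinguish cells
suitable by all $L$ variables ("red"), by exactly $L-1$ ("yellow"), and
the rest; with $L = 1$ the yellow class is undefined and only red/below
occur.

This deliberately simple model has two properties the workflow depends on:
each variable is treated independently, so each interval endpoint can be
reconstructed on the tree as its own continuous character; and the fitted
envelope always scores its own training cells 1, giving a built-in
self-consistency check.  Its known costs are also real: bounds are sample
extremes, so envelopes are underestimated at small sample sizes, and a
min–max box ignores correlations between variables.  Species with fewer
than ten localities are modelled anyway (a warning is logged): for narrow
endemics confined to a single climatic niche, additional points would
resample the same climate cell and leave the envelope unchanged, and a
minimal model is more useful downstream than a missing one.

## Evaluation and variable selection

Candidate variables are screened by fitting, for every species, a
single-variable envelope and scoring it with the rank-statistic AUC
against background cells:

$$\mathrm{AUC} = \frac{\#\{p > b\} + \tfrac12\,\#\{p = b\}}{n_p n_b},$$

over all presence–background score pairs.  Ties receive half credit
(the Mann–Whitney convention) — essential here because an envelope surface
takes at most $L + 1$ distinct values.  Background cells are drawn
uniformly at random, without replacement, from non-missing non-presence
cells ($n_b = \min(10\,n_p, 10^4)$ by default, seeded); how absences
should be generated is a genuinely open choice in presence-only
evaluation, and this default is standard practice made fully reproducible.
Species qualify for the per-variable mean AUC only when the analysis rests
on at least ten *environmentally unique* points — distinct climate-value
vectors over the modelled variables, read at cell resolution.  We compare
joint vectors (not per-variable values) because that is the strictest
reading that is still reproducible; it is configurable in the sense that
the count is computed on whatever variable set is passed.

Selection then removes redundancy: among the remaining pair of variables
with the largest correlation magnitude above the threshold (default
$|r| > 0.8$, Pearson, pooled over all species' points), the member with
the lower mean AUC is dropped, and the search repeats until no pair
exceeds the threshold.  Magnitude rather than signed $r$ is compared: a
correlation of $-0.95$ is as redundant as $+0.95$ (the two readings
coincide on the shipped reference table, which has no strong negative
pairs).  Mean-AUC ties keep the first-listed variable by default, or can
be made a hard error.  Two documented behaviours of this rule on the
shipped 16-variable reference table: the known tie between the
coolest-month and coolest-quarter temperatures (both 0.97, $r = 0.99$)
resolves to the first-listed, and applying the rule to the printed values
retains *five* variables — the warmest-quarter temperature survives
because its only strongly correlated partner has the lower printed AUC —
where the original analysis reports four.  Unrounded AUCs or an
undocumented step would explain the difference; the package reports what
the stated rule yields rather than forcing the published set.

## Ancestral reconstruction

Each envelope bound of each variable is an independent continuous
character evolving by Brownian motion with rate $\sigma^2$
(units$^2$/Ma).  The joint maximum-likelihood states at internal nodes
minimize $\sum_{\text{edges}} (\Delta s)^2 / \ell$, which makes every
internal state the inverse-branch-length-weighted mean of its neighbours'
states; paleoniche solves that linear system directly.  Profiling out the
internal states leaves the tip quadratic form
$(x - \hat\mu)^\top C^{-1} (x - \hat\mu)$ with $C$ the phylogenetic
covariance matrix, so the same minimized sum yields the ML rate
$\hat\sigma^2 = \mathrm{SS}/n$ (divisor $n$, the number of tips; the
$n-1$ variant is reported alongside) and the log-likelihood.  The test
suite checks the solver against an independent dense GLS oracle built
from explicit covariance inversion, to $10^{-8}$ relative error.

Because the states are branch-weighted averages, they obey the maximum
principle: every reconstructed value lies within the range of the tip
values for that character.  A corollary worth noting: when the lower and
upper bound are reconstructed on the *same* tree, both are the same
linear combination of tip values, so valid tip envelopes can never
produce a reconstructed $\max < \min$.  The midpoint-collapse repair rule
(both bounds replaced by their mean, with a log entry) is therefore a
safety net that cannot fire under the joint-ML estimator; it is kept
because the output contract promises valid envelopes regardless of how a
future estimator might behave.  Zero-length edges are collapsed by
merging their endpoints (shared state, with a warning); two tips with
different values at zero distance are an error, since the likelihood
degenerates.

The shipped reference tables for the ivesioid clade illustrate one
caveat of published fixtures: in the ancestral-bounds table, the Min
column of the coolest-month precipitation is numerically identical,
row by row, to the warmest-month Min column and lies *below* the minimum
tip value of its own character (0.0–0.2 against a tip minimum of 0.5) —
something no maximum-principle-respecting reconstruction can produce.
The corresponding regression test asserts containment for all eight bound
columns and is expected to fail for that one column; the package treats
the table as a shape/sanity fixture, not a numeric target (the underlying
chronogram's branch lengths were never published, so the values could not
be recomputed in any case).

## Node projections, overlap, and the age–range correlation

Nodes with posterior probability above 0.95 (strict; an unlabelled root is
included, since a consensus root is certain by construction) are projected
twice: into the scenario whose age is closest to the node's age (exact
ties resolve to the younger scenario) and into the present-day scenario,
so that differences between maps can be attributed to either the model or
the climate, never both at once.  No resampling is performed — each
projection uses the target scenario's native grid.

Niche overlap between two taxa is computed on suitability surfaces
normalized to probability surfaces over their *common* non-missing mask
(renormalized after masking, so differing coastlines do not masquerade as
niche differences):

$$D = 1 - \tfrac12 \sum_i |p_{X,i} - p_{Y,i}|, \qquad
  I = 1 - \tfrac12 \sum_i \left(\sqrt{p_{X,i}} - \sqrt{p_{Y,i}}\right)^2,$$

both in $[0,1]$, equal to 1 only for identical surfaces.  The age–range
correlation regresses pairwise overlap on the age of each pair's most
recent common ancestor.  Pairs sharing a taxon are not independent, so
the p-value comes from a permutation null that jointly relabels the rows
and columns of the overlap matrix, with add-one smoothing:
$p = (1 + \#\{|\beta^*| \ge |\beta|\}) / (1 + n_{\text{perm}})$.  The
parametric regression p-value is reported alongside for reference, since
published analyses do not always state which construction they used.
Adjusted $r^2$ uses $1 - (1 - r^2)(n-1)/(n-2)$ with $n$ the number of
pairs.

## The synthetic-data generator

Every stage is testable without external data because the generator
simulates complete studies with known truth:

* **Tree** — forward pure-birth (Yule) simulation from two crown lineages
  (default 38 tips, birth rate 0.17/Ma, giving crown ages of the order of
  15–20 Ma), with synthetic posterior probabilities so support filtering
  can be exercised.
* **Envelopes** — per variable, the envelope *centre* and *log-width*
  evolve as independent Brownian motions; bounds are centre $\mp$
  width/2, so simulated truth is always valid.  The inference stage still
  reconstructs min and max independently, as the analysis method
  prescribes — this deliberate mismatch probes that simplification.
  Default root bounds follow the published envelope table for the
  ivesioid clade's deepest node.  Default rates implement a
  niche-conservatism regime: drift standard deviation over the expected
  crown age of one quarter of the root envelope width for centres, and
  0.25 on the log-width scale.  This is the regime in which the
  end-to-end recovery contract (below) is meant to hold; rates matched
  instead to the raw dispersion of the published tip table are roughly
  2–4 times larger and degrade root recovery to ~70–80%.
* **Climate** — each variable is a spatially autocorrelated Gaussian
  field (separable smoothing, default scale 5 cells) blended with a
  latitudinal gradient (weight 0.4) and min–max rescaled to the
  variable's range; default grids are 100×100 cells of 0.1° over a Great
  Basin-like window, with an optional smooth "ocean" mask (8% of cells)
  shared across layers and ages.  Paleo scenarios (10, 8, 3 Ma) add a
  second smooth anomaly growing linearly with age.  By default each
  variable's range is derived from the simulated envelopes (their full
  span plus half a root width per side), the way a real study region's
  grids necessarily span the climates at the species' localities.  A
  random field draw can still leave some tip's joint climate condition
  unmet anywhere on the grid; such draws are rejected and the fields
  redrawn under a deterministic sub-seed (the tree and envelope truth are
  never redrawn), so every bundle honours the ground-truth contract that
  each occurrence sits in a fully suitable cell.
* **Occurrences** — default 100 per tip, drawn uniformly from the cells
  its true envelope scores 1, positioned uniformly within the cell.

All randomness flows from one integer seed through a fixed splitting
scheme, so any stage can be regenerated independently and bundles are
byte-reproducible.

What the generator does *not* emulate: spatial sampling bias and
georeferencing error in occurrence records, climate variables correlated
through shared physics (layers are independent fields plus a shared
gradient), dispersal limitation, and GCM-grade paleoclimate structure.
Passing tests therefore demonstrate that the implementation is correct
and internally calibrated, not that the method is robust to the biases of
real data.

## Calibration results carried by the test suite

The acceptance tests (in `tests/testthat/test-acceptance.R`) verify, among
exact oracle equivalences: that $\hat\sigma^2$ has relative bias below 10%
and root-state estimates are centred on truth (200 replicates on a 64-tip
tree); that the permutation p of the age–range correlation is uniform
under exchangeable overlaps (500 repetitions of 200 permutations,
Kolmogorov–Smirnov); and that the full pipeline recovers the true root
envelope with per-variable interval Jaccard ≥ 0.5 in at least 90% of 50
replicate studies at 32 tips and 100 occurrences per tip.  The residual
recovery failures decompose into Brownian sampling noise in the ML root
state (present even when the true tip envelopes are supplied) and the
~10% inward truncation of fitted envelope widths at 100 occurrences per
tip — both inherent to the method, not to the implementation.  Problem
sizes in the routine unit tests are smaller (8–12 tips, 40–60-cell grids),
chosen to exercise every code path with fast, deterministic fixtures.

## Numerical and convention choices

* Grids are cell-registered ESRI ASCII; values are written with the
  shortest decimal string that reparses to the identical double, so
  write/read round trips are bit-exact.
* Point-in-cell uses half-open intervals: columns $[x, x + c)$ west to
  east, rows $(y - c, y]$ south from the north edge, so every boundary
  point belongs to exactly one cell and the north edge to row 1.
* Cleaning replaces visual inspection with two deterministic rules:
  exact-duplicate removal and removal of points off-grid or on cells
  missing in any layer; the operation is idempotent and reports counts by
  reason.
* Coordinates are geographic lon/lat throughout; paleoclimate grids are
  used on modern coordinates, and no reprojection or resampling is ever
  performed.
* Envelope bounds are closed intervals, so degenerate (min = max)
  envelopes still match their own training cells.
* Trees must be rooted, binary, with non-negative lengths and unique tip
  labels; non-ultrametric trees are accepted with a warning, ages then
  measured from the deepest tip.

## Limitations

Exact reproduction of the published ivesioid numbers is out of reach by
construction: the occurrence records, BRIDGE climate grids and dated tree
behind them are not redistributable, the background scheme behind the
published AUC values is undocumented, and the chronogram's branch lengths
were never printed.  The shipped reference tables are used the only way
they can be: as structural fixtures (layouts, ranges, degenerate cases,
the maximum-principle check) and as the source of realistic defaults for
the generator.  Within those limits, every number the package reports is
recomputed from scratch by `scripts/acceptance.R` on synthetic data with
known truth.
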