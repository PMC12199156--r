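---
title: "Detecting metabolite-mediated cell-cell communication: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting metabolite-mediated cell-cell communication: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacomm)
```

## The problem

Cells exchange signals not only through protein ligands and receptors but
also through small metabolites: a *sender* population expresses the enzymes
that produce and secrete a metabolite, and a *receiver* population detects
it through a *sensor* protein. Sensors fall into three classes with
different biophysics: cell-surface **transporters** and **nuclear
receptors** require the metabolite to be taken up by the receiver, whereas
cell-surface **receptors** act at the membrane without uptake. `metacomm`
infers such metabolite-mediated cell-cell communication (mCCC) events from
a grouped (cell-type-annotated) scRNA-seq matrix together with a curated
metabolite-enzyme-sensor knowledgebase, and optionally constrains the
calls with metabolite efflux/influx estimates from an external
flux-balance tool.

## The score

For each metabolite $m$, cell group $g$, and the group-mean expression
$\bar{x}_g(\cdot)$ of its genes, the sender-side **enzyme aggregate** is

$$a(g, m) \;=\; \operatorname{mean}_{e \in \mathrm{prod}(m)} \bar{x}_g(e)
\;-\; \operatorname{mean}_{e \in \mathrm{cons}(m)} \bar{x}_g(e),$$

the average expression of the metabolite's producing enzymes minus that of
its consuming enzymes (zero if it has none). This is deliberately a
*qualitative* availability signal, not an abundance estimate: a group
dominated by consuming reactions gets a negative aggregate and — under the
default clamp — is treated as "not a producer". For a sensor gene $s$ of
$m$ and a receiver group $r$, the **co-expression score** is the product

$$S \;=\; \max(a(g, m),\, 0) \cdot \bar{x}_r(s).$$

The raw (unclamped) aggregate is retained in the output table for
transparency.

## Significance: a joint cell-label permutation null

All cell labels are shuffled jointly (group sizes preserved) and *both*
factors of $S$ are recomputed from the shuffled group means, for every
(sender, metabolite, sensor, receiver) combination, in each of `n_perm`
permutations (default 1000, seedable). Recomputing the two factors from
the same shuffled labeling preserves their dependence structure. The
one-tailed p-value uses the add-one convention,

$$p \;=\; \frac{1 + \#\{S^{\mathrm{null}} \ge S^{\mathrm{obs}}\}}{1 + n_{\mathrm{perm}}},$$

so $p \in [1/(n_{\mathrm{perm}}+1),\, 1]$ and ties count as exceedances
(conservative). Benjamini–Hochberg FDR is computed once over all events
scored in a run (every group pair crossed with every scorable
metabolite-sensor pair with $S > 0$); the default detection cutoff is
FDR < 0.05. The **communication score** normalizes the observed score by
its own permutation background,

$$C \;=\; \frac{S^{\mathrm{obs}}}{\max(\overline{S^{\mathrm{null}}},\, \varepsilon)},
\qquad \varepsilon = 10^{-8},$$

with events whose null mean hits the floor flagged `background_floor`.
The background is computed per event (per group pair and
metabolite-sensor pair), not pooled. Autocrine events (sender = receiver)
are scored like any others.

Two practical consequences of this construction are worth knowing:

* **Discreteness.** With $n_{\mathrm{perm}} = 1000$ the smallest
  achievable p-value is $1/1001$. In a BH family of $N$ events, the
  smallest achievable q-value is roughly $N/(1001\,k)$ where $k$ events
  sit at the floor; large families therefore need more permutations
  before anything can clear FDR 0.05. The spatial-evaluation analysis in
  this package uses `n_perm = 5000` for exactly this reason.
* **Receiver localization.** The permutation test asks whether the
  *product* beats its shuffled background. When a sender strongly
  over-expresses producing enzymes, the product exceeds the null for
  *every* receiver that expresses the sensor at all — the co-expression
  factor alone cannot tell which receiver is addressed. Receiver identity
  comes from the influx gate below; this is the role the flux constraint
  plays on real data too.

## Flux gating

Given group-by-metabolite efflux and influx matrices from any external
estimator (units treated as relative), an event is kept iff

* the sender's efflux for the metabolite **strictly exceeds** the efflux
  threshold, and
* when the sensor class requires uptake (transporter or nuclear
  receptor), the receiver's influx strictly exceeds the influx threshold;
  surface-receptor events are **exempt** from the influx condition.

Each threshold is the linear-interpolation percentile (default the 25th)
of that matrix's pooled scores; per-metabolite thresholds are available as
an option. Degenerate all-equal matrices therefore gate everything under
the strict comparison — this is documented and warned about rather than
patched. One special case: at percentile 0 the comparison becomes
$\ge$, because the 0th percentile *is* the minimum and the gate at
percentile 0 is meant to be the identity over positive fluxes. Gating
never alters scores, p-values or FDR of surviving events, and FDR is not
recomputed after gating (the gate is a post-hoc qualitative constraint).

## Evaluation procedures

* **Spatial colocalization.** From a spots-by-cell-type proportion matrix
  (the output of any spatial deconvolution tool), the colocalization of
  two cell types is the Spearman correlation of their proportions across
  spots. For each metabolite mediating events between at least
  `min_pairs` (default 10) distinct cell-type pairs, the per-metabolite
  correlation between communication scores (summed over sensors within a
  pair) and colocalization scores is reported; autocrine pairs are
  excluded because self-colocalization is trivially 1. With few cell
  types, proportions are compositional: rows sum to 1, which biases
  pairwise correlations slightly negative (about $-1/(G-1)$ under
  independence). Rank correlations do not remove this; it is a property
  of proportions, not of the estimator.
* **Robustness.** `downsample_cells()` takes a uniform random cell subset;
  `inject_noise()` adds $\lceil \rho \cdot \text{total reads} \rceil$
  reads uniformly over (cell, gene) slots at noise-to-signal ratio $\rho$,
  conserving original reads exactly. Detected-event sets are compared with
  two **recapture ratios**: the intersection over the perturbed set's size
  ("over total detected") and over the original set's size ("over
  originally detected").
* **Condition comparison.** Tables from several conditions are unioned on
  the event identity (sender, metabolite, sensor, receiver), with absent
  events scored 0 (absence of a detected event is informative). Each
  event's **index of dispersion** is its population variance over mean of
  communication scores across conditions (undefined when the mean is 0).
  Events are ranked by IOD and the top fraction (default 5%) selected;
  boundary ties are all included, zero-IOD events never are, and the
  achieved IOD cutoff is reported because it is dataset-specific.
  Selected profiles are z-scored per event (constant rows excluded) and
  clustered with k-means (default $k = 5$, 10 restarts, Euclidean
  distance, seeded).
* **Network summaries.** Per directed (sender, receiver) pair: event count
  and overall strength $\sum -\log_{10}(\mathrm{FDR})$.

## The synthetic-data generator

Counts are negative binomial with dispersion (size) 2 and log-normal
per-cell library factors (sdlog 0.3, mean-corrected). Enzyme and filler
genes share a baseline mean of 0.5; **sensor genes get a lower baseline of
0.05**. The separate sensor baseline is deliberate: transporters,
GPCR-class receptors and nuclear receptors are lowly expressed in real
scRNA-seq data, and it is precisely the regime where sensor expression is
limiting that makes the product score a two-factor test rather than an
enzyme-expression test. Planted events multiply the sender's producing
enzymes and the receiver's sensor gene by a fold change (default 4);
consuming enzymes are never boosted by planting. Decoy configurations
boost a group's *consuming* enzymes to verify that net consumers are not
called senders.

Synthetic flux matrices mirror the planted truth: planted sender/receiver
entries get $2 + U(0, 0.5)$, all other entries are exactly 0. A constant
non-planted level is the only construction in which the non-planted
majority falls at-or-below a pooled 25th-percentile threshold — any
spread in a majority class necessarily puts most of it above its own
lower quartile. Mock spatial data mixes a shared per-spot gamma factor
into each planted pair's intensities with weight
`colocalization_strength` (optionally scaled per pair by the planted fold
change), then normalizes rows to proportions.

### Scenarios and what they are sized for

* `default_scenario()` — 4 groups x 100 cells, 5 events at fold 4 over
  glucose, alanine and cholesterol. These metabolites share no genes with
  any other fixture metabolite, and all their sensors require uptake, so
  the influx gate can localize receivers; metabolites planted from two
  senders share one receiver so that every implied sender/receiver
  combination is part of the truth. One sibling-sensor call (cholesterol
  via NR1H3 instead of RORA) is expected and tolerated by the recovery
  check.
* `robustness_scenario()` — 8 groups x 120 cells, 20 events. Designed so
  the detectable event set is *discrete*: uptake-only sensors, all
  sensors of each planted metabolite planted, one receiver per
  metabolite, gene-disjoint metabolites. 120 cells per group keeps group
  means stable in a 50% down-sampled replicate, the regime the
  down-sampling analysis is about (the corresponding full-scale analyses
  run on tens of thousands of cells).
* `spatial_scenario()` — 8 groups x 100 cells; one sender per metabolite
  signalling to every other group at graded folds (8 down to 2), paired
  with fold-scaled mock spatial data. Per-metabolite correlation between
  communication and colocalization needs a within-metabolite gradient of
  both quantities; graded folds create it at this scale.

### What the generator does not emulate

No gene-gene correlation structure beyond the planted signal, no
batch/donor effects, no ambient RNA or doublets, no dropout model beyond
NB sampling, no realistic metabolic network coupling between enzymes.
Passing the planted-truth tests shows the statistical machinery is
correct and calibrated under the stated model; it does not by itself
guarantee performance on real tissues.

## Numerical and degenerate-input choices

* Permutation p-values use add-one; p is never 0; ties count against the
  event. The whole inference is deterministic given the seed.
* Negative enzyme aggregates are clamped before the product (default,
  switchable); clamped events have $S = 0$ and are excluded from the
  output table, hence can never reach significance.
* Groups with fewer than `min_cells` (default 3) cells are excluded with
  a warning; permutation means over tiny groups are unstable.
* Normalization is per-cell total-count scaling to $10^4$ followed by
  `log1p`, skippable for pre-normalized input; all-zero cells stay
  all-zero with a warning; group means are averaged on the (log-)
  normalized scale by default, with linear-scale input equally supported
  by passing untransformed matrices.
* An optional expression-fraction filter (minimum fraction of sender
  cells expressing a producing enzyme and receiver cells expressing the
  sensor) exists and is off by default.
* The index of dispersion uses the population variance (fixed, small
  condition counts); either convention is defensible and one must be
  chosen.
* `percentile_threshold()` is the type-7 (linear interpolation) quantile.

## Knowledgebase notes

The bundled fixture knowledgebase (11 metabolites, 17 sensor pairs,
all three sensor classes) exists so every stage is testable without
downloads; it is a miniature, synthetic-scale stand-in for the full
curated resource, which reports 432 metabolite-sensor partners in its
release description (440 in a later revision — both numbers are quoted
here without reconciling; the deposited file is authoritative). Loading
validates referential integrity (rows with unresolved metabolite ids are
rejected and reported, never silently dropped), merges duplicate pairs
across sources (multi-source pairs count as their own provenance
category), and flags metabolites lacking either a producing enzyme or a
sensor as inactive rather than deleting them.

## Known limitations

* The co-expression score cannot localize receivers without flux
  information (see above); interpret ungated results at the
  (sender, metabolite) resolution.
* BH q-values inherit permutation granularity; with large event families
  and few permutations nothing can be significant. Increase `n_perm`
  rather than relaxing the cutoff.
* Flux gating trusts the external estimator; thresholds are relative
  percentiles, not absolute rates.
* The FDR family is defined per run; merging tables across runs and
  re-thresholding is not supported and would invalidate the FDR.
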