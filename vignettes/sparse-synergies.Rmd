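---
title: "Identifying sparse muscle synergies from burst phase data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying sparse muscle synergies from burst phase data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsesynergy)
```

## The problem and the model

During locomotion, each muscle produces one or more bursts of EMG activity
per step cycle. A *sparse synergy* is a small group of such bursts that start
and stop together — a definition grounded in burst timing rather than in a
weighting matrix over all muscles, which is what factorization methods
(NNMF, PCA, ICA) produce. This package identifies sparse synergies from
tabular burst observations, one row per muscle burst per step cycle.

Times are first converted to **step-cycle phase**: the cycle runs between two
successive onsets of a reference muscle (a swing-onset flexor such as the
brachialis), is normalized to unit length, and events before the reference
onset carry negative phase. Each burst is then a point cloud in the
(onset, offset) phase plane, summarized by its centroid
$P_i = (X_i, Y_i)$, SD vector $S_i = (\sigma_{Xi}, \sigma_{Yi})$, trial
correlation $\rho_i$ and trial count $n_i$.

Two bursts are *associated* when their $\pm 1$ SD rectangles overlap along
the axis joining their centroids. With $d = P_i - P_j$ and
$\hat d = d / \lVert d \rVert$,

$$q_{ij} = \left(|\sigma_{Xi}\hat d_x| + |\sigma_{Yi}\hat d_y|\right)
         + \left(|\sigma_{Xj}\hat d_x| + |\sigma_{Yj}\hat d_y|\right)
         - \lVert d \rVert,$$

and $q_{ij} > 0$ declares the pair adjacent. The two projection terms are
the maxima, over the four vertex sign choices of each rectangle, of the SD
vertex vector projected on $\hat d$ — the vertex facing the neighbour. This
geometric form is translation-invariant and scale-equivariant, and coincident
centroids are treated as adjacent. A boolean adjacency matrix over all pairs
is reduced to its equivalence classes (connected components, computed by
union–find), and the resulting clusters — the synergies — are renumbered so
their mean onsets ascend. Transitivity is deliberate: a chain of pairwise
overlaps forms one synergy even if its extremes do not overlap directly, and
a burst belongs to exactly one synergy.

Before summarizing, each burst's trials pass an iterative outlier screen in
the spirit of Rosner's generalized ESD test: the trial deviating most from
the current mean, in SD units of either coordinate, is removed if it exceeds
a 2 SD margin, with statistics recomputed after every removal. The test
statistic is per-coordinate; a removal cap of 10% of the trials keeps the
screen from eroding genuinely broad bursts (the test names its margin but
not a maximum outlier count, so the cap is this package's choice).

## Two-substage and constrained clustering

When bursts come from several animals, clustering proceeds in two
sub-stages: the most complete animal's bursts are clustered alone, then the
remaining bursts are admitted one at a time in ascending onset order. A
candidate may join a multi-member cluster only if it is adjacent to **at
least two** of its members; a singleton cluster admits on one adjacency.
Bursts that join nothing are clustered among themselves. The processing
order and all tie-breaks (most adjacent members first, then nearest
centroid, then lexicographically first label) are fixed, so the result is
deterministic; plain single-stage clustering is order-invariant outright.

Comparing conditions (unobstructed walking vs the lead and trail limbs of an
obstacle step) is confounded if the synergy composition itself changes, so
the package also offers a **constrained** mode: bursts keep the cluster
membership they had in a reference solution (normally the unobstructed
condition), regardless of where their centroids moved. Bursts present only
in a gait-modification condition are routed through the adjacency matrix to
the cluster with the greatest number of adjacent members (ties by nearest
centroid; a burst adjacent to nothing falls back to the nearest centroid
with a warning). Pooled statistics are always recomputed from the
condition's own trials. `compare_solutions()` tabulates, per constrained
cluster, the unconstrained clusters sharing members and the centroid
distance of each pair, which is how composition changes between the two
analyses are quantified.

## Direct components and ellipses

Each cluster gets a *direct component* (DC): a piecewise-Gaussian temporal
activation profile computed directly from the pooled phase statistics,
peaking at $Z = (X+Y)/2$ with side widths
$\sigma_1 = (Z-X)/3 + \sigma_X$ and $\sigma_2 = (Y-Z)/3 + \sigma_Y$ and
nominal support $(X - 3\sigma_X,\, Y + 3\sigma_Y)$. The exponent is
$\exp\!\left(-(t-Z)^2 / 2\sigma^2\right)$: the squared-denominator form
makes each side a proper Gaussian in phase units and keeps
$u(Z \pm \sigma) = e^{-1/2}$; a `literal` mode with an unsquared
$2\sigma$ denominator is exposed for comparison, since the two conventions
differ and the choice matters for profile width. Tails are evaluated beyond
the nominal support rather than truncated; the support is metadata. The
default output grid is 1,000 uniform points over phases $-0.5$ to $1.5$.

Phase-plane scatter is displayed through the correlated bivariate-normal
1-SD contour $u^2 + v^2 - 2uv\rho = 1 - \rho^2$ in standardized coordinates.
Points are generated by the exact parameterization
$u = \cos\theta$, $v = \rho\cos\theta + \sqrt{1-\rho^2}\,\sin\theta$, and the
contour touches its $\pm 1$ SD rectangle exactly at
$(u, v) = (\pm 1, \pm\rho)$ and $(\pm\rho, \pm 1)$, which
`ellipse_tangency()` returns. Degenerate bursts with zero variance get
$\rho := 0$.

## Condition statistics

For each synergy, the per-trial onset, offset, peak phase
($(\text{onset}+\text{offset})/2$, computed per trial rather than from the
means) and duration-normalized magnitude of all member bursts are pooled and
tested across conditions with a one-way fixed-effects ANOVA; measures with a
significant condition effect (at $\alpha = 0.05$) get pairwise two-sample
t-tests. The t-tests use Welch's correction — the variance-homogeneity
assumption is not defensible when gains differ fourfold between conditions —
and raw pairwise p values are reported by default, with a Bonferroni option.
Burst magnitude is the envelope integral over 1-ms bins divided by burst
duration in ms, i.e. mean activity per ms, which makes it invariant to
duration changes; condition magnitudes are expressed as a percentage of the
control mean, undefined for bursts inactive in control.

## What the synthetic generator emulates

No recordings accompany the method, so the package ships a generator whose
defaults (`figure2_config()`) are the study conditions: 10 clusters over 27
bursts of 18 muscles from 3 animals, 30–70 trials per burst, bivariate
normal scatter with $\sigma \approx 0.02$ cycle and $\rho = 0.4$,
nearest-neighbour centroid separations of roughly 0.11–0.23 cycle, eight
clusters around swing (three of them before swing onset, at negative phase)
and two extensor clusters in stance. Condition effects are planted where the
qualitative findings put them: the trail condition advances the pre-swing
clusters 1–3 by 0.05 cycle and amplifies clusters 2–3 by a factor of 4; the
lead condition delays late-swing clusters 7–8 by 0.05 cycle and amplifies
the transport clusters 3–6 by a factor of 2; a handful of novel bursts exist
only in the gait-modification conditions. Per-burst centroid offsets within
a cluster are bounded at 0.005 cycle, and per-trial magnitudes are lognormal
(positivity) with a coefficient of variation of 0.2. Since the published
geometry is only qualitative, the exact centroids are this package's choice,
made once; members of the same muscle were placed so their burst windows
never overlap in time, which the envelope generator enforces.

The generator emulates burst timing statistics, not electrophysiology: there
are no motor-unit potentials, no filtering artefacts, no cycle-to-cycle
correlation, no interlimb structure, and condition shifts are constant
offsets rather than obstacle-scaled curves. Passing tests therefore
demonstrate that the algorithms recover known structure under the planted
statistical model — not that real EMG meets that model.

The jitter experiment probes robustness the same way the method's stability
was originally argued: every burst centroid is displaced by a uniformly
random vector of norm below 0.6 times that burst's SD magnitude
$\lVert(\sigma_X, \sigma_Y)\rVert$ (the displacement norm is this package's
reading of "0.6 SD"; all bursts are jittered independently per replicate),
clustering is re-run, and the unchanged fraction over 1,000 replicates is
reported.

## Numerical choices and problem sizes

* Trials are put in a canonical order (cycle, onset, offset) before any
  summary, and all output floats carry 6 significant digits, so repeated
  runs — including runs on row-permuted input — are byte-identical.
* Cluster centroids are unweighted means of member burst centroids; pooled
  statistics are additionally kept trial-weighted (combined exactly from
  per-burst sufficient statistics) for the DCs. Whether published centroid
  distances weight by trial count is not stated; both quantities are
  available.
* Degenerate statistics resolve to limits: identical centroids are adjacent
  ($q = \infty$), zero-variance correlation is 0, an all-equal ANOVA gives
  $F = 0, p = 1$, zero within-variance with unequal means gives $p = 0$.
* Phase is treated as linear, not circular; bursts are assigned to the cycle
  whose window $[\text{start} - 0.5\,\text{dur}, \text{end} - 0.5\,\text{dur})$
  contains their onset, so pre-reference bursts land in $[-0.5, 0.5)$.
  Offsets past the next reference onset keep phase $> 1$ without
  reassignment.
* The test suite sizes its simulations to run comfortably on one CPU:
  10,000 random pairs for the adjacency oracle, 1,000 random graphs for the
  component oracle, 100 generator seeds for partition recovery, 1,000 jitter
  replicates, and 5,000 null ANOVA replicates for calibration.

## Worked example

```{r example, eval = FALSE}
cfg <- figure2_config()
d <- generate_burst_dataset(cfg, seed = 7)
bt <- d$bursts

st <- summarize_bursts(bt[bt$condition == "unobstructed", ])
sol <- cluster_bursts(st)
sol                      # 10 clusters, ids ascending in onset

trail <- assign_constrained(summarize_bursts(bt[bt$condition == "trail", ]), sol)
cmp <- compare_conditions(bt, sol)
head(cmp$anova)          # condition effects per synergy and measure

res <- run_pipeline(pipeline_config(bt, out_dir = tempdir()))
```

## Limitations

Burst boundaries must be supplied; the package does not detect onsets or
offsets from raw EMG, nor does it filter or rectify signals. Labels must
identify the same period of activity across conditions for the constrained
mode to be meaningful. The adjacency criterion assumes each burst is
adequately described by an axis-aligned SD rectangle (the trial correlation
enters the ellipse display and pooled statistics, not the clustering
itself), and transitive merging can chain distinct groups through an
intermediate burst — the jitter experiment is the intended check on that
fragility for a given dataset.
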