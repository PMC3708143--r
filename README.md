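# sparsesynergy

Sparse muscle synergies from locomotor EMG burst timing.

During walking, each muscle fires one or more bursts per step cycle. A
*sparse synergy* is a small group of bursts that begin and end together —
a timing-based definition, in contrast to factorization methods (NNMF, PCA,
ICA) that spread every synergy across all muscles. This package is for
motor-control researchers who have marked burst onsets and offsets (e.g. in
cat or human locomotion) and want to identify synergies, compare them across
walking conditions, and summarize them as activation profiles.

## Method

Burst events are expressed as phases of a unit-normalized step cycle
(reference-muscle onset = phase 0; earlier events are negative). Each burst
*i* becomes a centroid *P*ᵢ = (*X*ᵢ, *Y*ᵢ) and SD vector
*S*ᵢ = (σ*X*ᵢ, σ*Y*ᵢ) in the (onset, offset) phase plane. Two bursts are
associated when their ±1 SD rectangles overlap along the inter-centroid
axis: with *d* = *P*ᵢ − *P*ⱼ and *d̂* = *d*/‖*d*‖,

    qᵢⱼ = (|σXᵢ d̂x| + |σYᵢ d̂y|) + (|σXⱼ d̂x| + |σYⱼ d̂y|) − ‖d‖ ,

and *q*ᵢⱼ > 0 marks the pair adjacent. Equivalence classes (connected
components, via union–find) of the adjacency matrix are the synergies,
numbered by ascending mean onset. The package also provides:

* an iterative 2-SD outlier screen per burst (generalized-ESD style);
* two-substage clustering for multi-animal datasets (new bursts join an
  existing multi-member cluster only when adjacent to ≥ 2 of its members);
* a **constrained** mode that fixes synergy composition to a reference
  condition so phase/magnitude changes can be compared like-for-like, with
  adjacency-based routing of bursts that appear only in a new condition;
* **direct components**: piecewise-Gaussian activation profiles peaking at
  *Z* = (*X*+*Y*)/2 with widths σ₁ = (*Z*−*X*)/3 + σX, σ₂ = (*Y*−*Z*)/3 + σY;
* correlated bivariate-normal 1-SD ellipses
  (u² + v² − 2uvρ = 1 − ρ², tangent to the SD rectangle at (±1, ±ρ), (±ρ, ±1));
* one-way ANOVAs and Welch pairwise t-tests for phase and
  duration-normalized magnitude across conditions;
* a synthetic burst generator with planted ground truth (10 clusters,
  27 bursts, 30–70 trials per burst) plus a centroid-jitter robustness
  experiment.

## Worked example

```r
library(sparsesynergy)

d  <- generate_burst_dataset(figure2_config(), seed = 7)
bt <- d$bursts

st  <- summarize_bursts(bt[bt$condition == "unobstructed", ])
sol <- cluster_bursts(st)
sol
#> cluster_solution (unconstrained): 10 clusters over 27 bursts
#>   #1 [X=-0.323, Y=-0.204] Bic(1)
#>   #2 [X=-0.182, Y=-0.040] TrM(1), AcD(1), LtD(1), EDC(1)
#>   #3 [X=-0.063, Y=0.071] PrT(1), BrR(1), SpD(1)
#>   #4 [X=0.020, Y=0.189] Br(1)
#>   #5 [X=0.081, Y=0.298] Bic(2), ClT(1), ClB(1)
#>   ...
```

Ten synergies, ordered by mean onset: cluster 2, for instance, groups the
shoulder retractors and digit extensor (TrM, AcD, LtD, EDC) active just
before swing onset. Comparing conditions with the composition constrained to
this solution:

```r
cmp <- compare_conditions(bt, sol)
cmp$anova[cmp$anova$synergy_id == 2, ][1:4, ]
#>   synergy_id   measure    F df1 df2         p
#> 5          2     onset  399   2 591 2.12e-110
#> 6          2    offset  421   2 591 1.86e-114
#> 7          2      peak  603   2 591 1.82e-143
#> 8          2 magnitude 2322   2 591 1.15e-280
```

Synergy 2's onset, offset, peak phase and magnitude all differ strongly
across conditions — the generator plants a 0.05-cycle phase advance and a
4× magnitude gain on this cluster in the trail condition, and the analysis
recovers both (trail magnitude ≈ 407% of control in this run). Its direct
component summarizes the activation profile:

```r
solution_dcs(sol)[[2]]
#> direct_component #2: Z=-0.1112 sigma1=0.0427 sigma2=0.0423 amp=1.000 support=(-0.2392, 0.0157)
```

`run_pipeline(pipeline_config(bt, out_dir = "out"))` executes the whole
chain (screen → summarize → cluster → constrain → DCA → statistics) and
writes `clusters_<condition>.json`, `dc.csv`, `report.csv`, `magnitude.csv`
and `mapping.csv`; outputs are byte-identical across reruns. A command-line
front end with `cluster`, `dca`, `compare`, `simulate` and `jitter`
subcommands lives in `inst/scripts/synergy-cli.R`.

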