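---
title: "Methods: quantifying collective freezing decisions after a looming stimulus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying collective freezing decisions after a looming stimulus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomsync)
```

This vignette documents the models, rules and numerical choices behind
`loomsync`: what each stage assumes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where genuinely open
design decisions were settled.

## The assay and its data

Groups of six fish swim in a shallow tank (inner long side 20.0-20.5 cm;
water ~6 cm). A looming stimulus (LS) - an expanding dark disc on a monitor -
is presented repeatedly (5 presentations per day on two consecutive days,
i.e. 10 trials per group). For each trial, three 10-second windows are
analysed at 5 fps: before, during and after LS, so every individual-trial is
a 150-frame speed series. The familiar design has 17 groups (fish co-housed
for a month); the unfamiliar design has 12 groups formed the same morning.

`loomsync` starts from tracking CSVs (`frame,id0_x,id0_y,...`, video
coordinate convention) plus a JSON sidecar with units and frame rate. Pixel
coordinates are converted to cm by dividing by `pixels_per_cm`, measured from
the tank's inner long side (`calibration_spec()` warns when the reference
length is outside 20.0-20.5 cm).

## Speeds and the velocity matrix

Speed at frame $i$ is the Euclidean displacement from frame $i-1$ times the
frame rate (cm/s). Two edge conventions are deliberate:

* **First frame** - duplicated from frame 2, keeping exactly 150 frames per
  trial and hence exact 50/50/50 interval blocks. At most 1 of 150 frames is
  affected.
* **Smoothing** - a *trailing* moving average (window 5), with partial
  windows over the first four frames. A trailing window matches the common
  rolling-mean default, and partial leading windows avoid discarding frames
  at interval starts. Smoothing is applied to the assembled velocity matrix
  row by row, so the window does cross interval boundaries; the interval
  rules below are tolerant to the at-most-4 contaminated frames.

The velocity matrix stacks one row per individual-trial ordered by (group,
trial, individual): 1020 x 150 for the familiar design.

## Behavioural states

Frames are typed by smoothed speed: freezing-like (< 0.2 cm/s, strict),
high-speed (>= 6 cm/s, inclusive), normal otherwise. Each 10-s interval
becomes one state:

* **HS** if high-speed swimming is sustained for >= 0.2 s (one frame at
  5 fps) - escape bursts are that fast;
* otherwise **FS** if *total* freezing time is >= 8 s;
* otherwise **NS** (which, by the < 2 s rule for clean normal intervals,
  also absorbs intervals with 2-8 s of freezing).

Three decisions here were genuinely open and are configurable:

* "persisted for >= 8 s" is read as **total** freezing within the interval,
  not the longest consecutive run - it is paired with a "< 2 s" rule that
  reads naturally as a total;
* when HS and FS criteria co-occur, **HS wins** (`precedence` argument): the
  HS rule is a detection rule for rapid escape and a single frame is its
  defined trigger;
* intervals with intermediate freezing fall to NS so that the three states
  are exhaustive and the 27-pattern space (3^3 ordered triples) is complete.

### Data-driven thresholds

`derive_thresholds()` recovers both speed cut-offs from a velocity matrix the
way they were originally motivated: the post-LS speed distribution is
bimodal (freezers vs swimmers) and `v_freeze` is the kernel-density trough
between its two largest modes; the pre-LS distribution contains essentially
no escape-like speeds, and `v_high` is the smallest speed above which the
pre-LS density stays below 1% of its peak. Numerical choices:

* the trough search uses a fixed bandwidth of 0.03 cm/s. The freezing mode
  is ~0.1 cm/s wide, and rule-of-thumb bandwidths (nrd0) computed on the
  full bimodal mixture over-smooth it, displacing the trough upward by
  ~0.15 cm/s;
* the tail search uses nrd0 - there a smooth global density is wanted;
* modes count toward bimodality only if they reach 5% of the peak height
  and the trough dips below 80% of the lower mode; anything else triggers a
  loud fallback to the defaults (0.2, 6.0 cm/s).

On default synthetic data the derived values are ~0.20-0.24 cm/s and
~5.7-6.0 cm/s.

## Transition statistics

Markov transition matrices for before->during and during->after are raw
transition counts row-normalised to probabilities; rows with zero counts are
flagged, not divided. Diagrams are emitted as Graphviz DOT text (9 nodes = 3
states x 3 intervals; node size proportional to occupancy, edge labels the
transition probabilities).

Pattern enrichment tests each of the 27 triples against the null that all
patterns are equally likely ($p_0 = 1/27$): the p-value is the exact binomial
upper tail $P(X \ge k)$, one-sided because the question is whether patterns
occur *more* often than chance. FDR control is Benjamini-Hochberg over the
full 27-pattern family - zero-count patterns stay in the family with
$p = 1$, where they cannot create false positives. Stars follow `***`
q < 0.001, `**` q < 0.01, `*` q < 0.05. All 27 dimensions are retained
throughout (some real datasets have only ~23 patterns with nonzero counts;
keeping the zeros costs nothing and keeps the feature space fixed).

## The group-synchrony test

For each trial the number of FS individuals after LS is counted (0-6). Under
the null that individuals respond independently, virtual datasets are built
by permuting the binary FS indicators **across groups within each trial
index** (1000 replicates, seeds 1..1000 by default; a `global` pooling mode
exists because the within-trial reading of "shuffling the states of each
trial among groups" is one of two defensible parses). Each permutation
preserves the marginal FS prevalence exactly. The observed 7-bin histogram
is compared to the null by a plug-in chi-square: expected counts are the
averaged null proportions times the observed trial total, df = 6 (bins with
zero expectation are merged into a neighbour, reducing df, and flagged).
Only the after-LS FS indicator is shuffled - it is the only quantity the
test statistic consumes.

Calibration and power are verified in the test suite: with `coupling = 0`
(independent fish) the test rejects at the nominal 5% rate over 500
simulated experiments; in the consensus regime it rejects at
$\alpha = 0.001$ in >= 95% of experiments and the FS-count histogram is
bimodal at 0 and 6.

One refinement matters when checking the shuffle null against closed form:
because the permutation conditions on the realised prevalence $\hat p$, its
expected histogram is the binomial law at $\hat p$, not at the generating
probability; the correctness check therefore compares against
$\mathrm{Binomial}(6, \hat p)$ (and only loosely against the nominal law,
whose distance is dominated by the experiment's own sampling error).

## Group response profiles

Each group's 60 individual-trials give a 27-dim vector of pattern
frequencies (rows sum to 1). PCA (centred, unscaled) keeps the smallest
number of components exceeding 95% cumulative variance (`d95`). Clustering
is **spectral clustering on the PCA scores**: a symmetrised k-nearest-
neighbour connectivity graph, symmetric normalised Laplacian, k smallest
eigenvectors row-normalised, then k-means (nstart 50, seeded). The number of
clusters is chosen by the mean silhouette width computed in the same PCA
space over a default grid of 2-6 (the grid is a package choice; it brackets
the plausible structure for 12-29 groups).

Two robustness choices for small n:

* the neighbourhood starts at `max(2, floor(log n))` - larger neighbourhoods
  bridge compact clusters of 3-4 groups into their neighbours;
* if the graph has more connected components than k (near-duplicate
  profiles fragment a 2-NN graph), the neighbourhood grows until components
  <= k, since extra zero-eigenvalue components make the bottom eigenspace
  ambiguous.

The 2-D embedding used for inspection is classical metric MDS
(`stats::cmdscale`) of the PCA scores. It is deterministic, preserves the
cluster separation (nearest-neighbour purity >= 0.9 on planted archetypes),
and is **never** used for clustering - the ambiguous choice between
clustering in the reduced space versus a 2-D embedding is resolved in favour
of the higher-fidelity space, with the embedding as visualisation only.

FS counts are compared across clusters or conditions with a binomial-logit
mixed model: response `cbind(fs, 6 - fs)`, fixed effects as requested
(cluster identity and/or familiarisation), random intercepts for group
identity and trial number (and experiment identity when present), fitted by
`lme4::glmer`, with Tukey-adjusted pairwise contrasts via `multcomp::glht`.
Complete separation (a fixed-effect level with all-0 or all-6 counts) and
non-convergence are *flags* on the result, never silent failures: degenerate
all-or-none data are a real outcome of this assay.

## The synthetic-data generator

No raw data accompany the assay, so the generator is a first-class module.
It emulates the study conditions - 17 (or 12) groups of 6, 10 trials, 5 fps,
a 20.25 x 14.5 cm arena (midpoint of the stated 20.0-20.5 cm inner length,
by the tank's short side) - and the statistical structure the analysis
assumes, via two layers.

**Decision layer** (`simulate_states()`). Each group draws an archetype:
freeze-dominant, non-freeze or mixed, with mixture weights 0.40/0.35/0.25
and per-archetype log-odds of post-LS freezing (2.2 / -3.0 / -1.5) and of
escaping during LS (offsets +1.4 / -2.2 / +0.8 around a base escape
probability of 0.5). Escaping boosts the freezing intention by
`qlogis(0.7)` (70% of escapers freeze). Group consensus is a two-stage
draw: independent intentions first, then the majority direction $D$ is
formed and every fish redraws with `coupling` x (+-1) added on the logit
scale. `coupling = 0` reduces *exactly* to independent Bernoulli
individuals (the calibration regime); `coupling = Inf` forces unanimity;
the default 4 produces the bimodal all-or-none histograms. Archetypes are
drawn from the weights by default; `archetype_assignment = "balanced"`
plants them with deterministic largest-remainder counts - the stratified
design used by the recovery experiments, since a randomly drawn archetype
can land on only two groups, which no clustering method should be expected
to resolve.

**Rendering layer** (`simulate_trajectory()`). Freezing is uniform jitter
below 0.05 cm/s; normal swimming is a correlated random walk whose log speed
follows an AR(1) process (lag-1 autocorrelation 0.92, marginal mean 1.5 and
sd 1.3 cm/s) hard-capped at 5.7 cm/s - a burst-and-coast-like profile whose
smoothed density has a tail approaching, but never crossing, the 6 cm/s
threshold; escapes are 3 consecutive frames at 12 cm/s aimed at the farthest
corner (so a burst never shortens against a wall). Three frames at 12 cm/s
are the minimum that survives the window-5 trailing average at >= 6 cm/s; a
1-frame burst would smooth to < 6 cm/s and be undetectable by the classifier
the data are meant to exercise. Walls reflect (displacements of any
magnitude are folded back), and centroid tracking noise of sd 0.01 cm is
added - it gives the freezing speed mode its realistic width, which is what
places the post-LS density trough near 0.2 cm/s.

With these defaults the downstream classifier recovers the ground-truth
state triple for ~100% of individual-trials (the contract is >= 99%).

**What the generator does not emulate:** social interactions during
swimming (positions are independent given states), posture, wall-following
and thigmotaxis, day-1 vs day-2 habituation, stimulus-position effects, and
identity-swap tracking errors. Passing tests on synthetic data therefore
demonstrate that the *pipeline* is correct and well-calibrated under the
assay's statistical structure - not that any particular biological
conclusion holds for real fish.

## Problem sizes and runtime

The test suite verifies calibration with 500 simulated experiments (300
shuffle replicates each), power with 100, GLMM coverage with 100 refits, and
classifier-oracle agreement on 10,000 random intervals; the full suite runs
in a few minutes on one CPU. These sizes give binomial 99% confidence
intervals tight enough to detect miscalibration of a 5% test to within
+-2.5 points while keeping the suite convenient to run routinely.

## Known limitations

* The interval rules are threshold-based; fish hovering exactly at a
  threshold can flip states with tiny speed perturbations. The provenance
  columns (`freeze_s`, `high_frames`) expose the margins.
* The plug-in chi-square treats the averaged null proportions as known;
  with very few shuffle replicates the statistic inflates slightly.
* Spectral clustering cannot recover planted clusters of fewer than ~3
  groups (the affinity graph bridges them); the silhouette may then prefer
  a coarser k.
* `derive_thresholds()` assumes the post-LS mixture is genuinely bimodal;
  datasets without freezing fall back to the conventional thresholds with a
  warning rather than inventing a trough.
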