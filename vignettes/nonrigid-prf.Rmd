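---
title: "Non-rigid population response fields: model, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-rigid population response fields: model, fitting and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrprf)
```

## The model and its assumptions

A population response field (pRF) describes how the pooled neural activity
inside one imaging vertex is tuned over a set of features — here, the
movements of 18 body parts ordered as on the classical cortical homunculus
(toes = 1 … tongue = 18). Conventional pRF models fit a Gaussian
`exp(-(x0 - x_i)^2 / (2 sigma^2))` over that *rigid* axis, which builds the
homunculus ordering into the model. The non-rigid model removes that
assumption: the Gaussian field is frozen at centre 0 and sd 1, and each
body part's distance `dx_i >= 0` to the field centre is a free parameter,

$$g_i = \exp(-dx_i^2 / 2), \qquad dx_i \in [0,\ dx_{max}],\ dx_{max} = 10.$$

Only one flank of the Gaussian is used (distances are non-negative): with a
symmetric field a sign would be unidentifiable and would fabricate a
left/right relationship between body parts. At `dx = 10` the unit Gaussian
is numerically zero (`exp(-50) ≈ 2e-22`), so the bound only stops distances
from drifting arbitrarily once a part has left the field.

The forward model multiplies the weights into the binary task design
(condition × volume), convolves with a canonical HRF per run, and scales by
a single amplitude `beta` (Gaussian noise otherwise). Assumptions worth
stating: the response field is Gaussian in shape (other shapes are not
explored), the HRF is fixed and shared across vertices, noise is iid over
volumes, and responses add linearly over conditions.

Derived per-vertex summaries:

* **centre** — `which.min(dx)`; exact ties within `1e-6` take the *floor*
  of the mean tied index (ties are a measure-zero event in practice, and
  the floor keeps the centre integral).
* **size** — `sum(P(dx_i)) * FWHM/2` over parts inside the half-window
  `dx <= FWHM/2` with proximity `P(d) = (dx_max - d)/dx_max` and
  `FWHM = 2\sqrt{2\ln 2} ≈ 2.355`. A size of 1 means roughly one body part
  in the field; 18 parts at the centre give the maximum ≈ 21.2.

## How the fit is actually solved

The fitting surface looks like an 18-dimensional box-constrained nonlinear
least-squares problem, but it has special structure. Writing `X` for the
T × 18 matrix of per-condition HRF-convolved regressors, the prediction is
`beta * X g` with `g` in the positive box `(0, 1]^18`. Since `beta` is an
unconstrained scalar, the set of attainable predictions is exactly
$\{X c : c \ge 0\} \cup \{X c : c \le 0\}$: every signed positive
combination of regressors, no more and no less. The global least-squares
fit is therefore obtained by two sign-constrained (Lawson–Hanson) linear
solves — one on `y`, one on `-y` — picking the better. No multi-start
iterative search is needed, the solution provably attains the global
optimum (the test suite checks it against an exhaustive `0.25`-step lattice
on small problems), and a vertex fits in milliseconds.

The same structure exposes a scale ridge: the residual depends only on
`c = beta * g`, so `beta` and the distance vector trade off along
`dx_i^2 = -2 (\log c_i - \log beta)`. The fit is anchored by the convention
`max(g) = 1`: the preferred body part sits exactly at the field centre,
which matches how the synthetic ground truth is defined and keeps sizes
comparable across vertices. Parts with a zero coefficient are reported at
`dx_max`; distances much beyond ~6 are inherently unidentifiable because
their weights are smaller than any realistic noise floor.

Negative-amplitude fits are allowed and flagged (`negative_beta`), constant
timeseries produce a degenerate fit (`r2 = 0`, `p = 1`), and a `converged`
flag is carried for the conventional model, which really is nonlinear (two
parameters `x0 in [1, 18]`, `sigma in [0.1, 20]`) and is solved by bounded
Levenberg–Marquardt from a 36-point multi-start grid (`x0 in 1..18`,
`sigma in {1, 3}`).

## Goodness of fit and vertex selection

Each vertex gets an F statistic against the zero-signal null with
hypothesis df equal to the parameter count (18 distances + amplitude = 19;
the data are mean-free percent-change, so no intercept) and error df
`T - 19` — at the full protocol length `T = 856` that is (19, 837). One
property of this convention deserves emphasis: the model's prediction set
is an 18-dimensional positive *cone*, not a 19-dimensional linear subspace,
so under a true null the explained sum of squares falls well short of a
19-df chi-square and the test is **conservative**. Monte-Carlo calibration
in the test suite (2000 pure-noise vertices) puts the empirical rejection
rate near 0.2% at nominal 5%. Selected vertices are therefore a
high-confidence set; the Benjamini–Hochberg step-up (default `q = 0.05`)
inherits the conservatism and retains fewer than `q` under the null.

## The task, its schedule and the design matrix

The 18 parts are cued in two run-parts (part 1: abdomen…thumb; part 2:
toes/ankle/knee plus the face), each recorded in two runs of 237 and 191
volumes at TR 2.1 s — 856 volumes in total. Each condition is cued 9 times;
cue order is pseudo-randomised by rejection sampling until no condition
repeats back-to-back, and the interval following a cue is 10 s except for
exactly one randomly chosen repetition per condition, which is followed by
14.7 s. Choices the task description leaves open, fixed here:

* **Regressor duration** — a 3 s boxcar from cue onset (1 s forward cue,
  1 s gap, 1 s backward cue), configurable; impulse regressors
  (`boxcar = 0`) are supported.
* **Volume overlap** — a volume is "on" when its half-open acquisition
  window `[t, t + TR)` intersects the event window. With a 3 s boxcar on a
  2.1 s grid an event covers 2 or 3 volumes depending on onset phase, so
  exact event-count conservation holds only for TR-aligned onsets (tested
  both ways).
* **Packing** — 9 repetitions split 5 + 4 over a part's two runs, first
  cue 4 s after run start; this fits the 191-volume run even in the worst
  case where all nine long intervals land there.
* **HRF** — double-gamma: peak delay 6 s, undershoot delay 16 s, unit
  dispersions, undershoot ratio 1/6, sampled at TR, unit peak. All
  parameters are exposed.

## Aggregation, graphs and their conventions

The mean body-part response field of an ROI averages *untruncated*
proximity profiles `(dx_max - dx)/dx_max` over selected vertices sharing a
centre — untruncated because distant parts carry graded, nonzero proximity
in the displayed fields; truncation at the half-window is reserved for the
size metric. With several subjects the mean is computed per subject and
averaged with equal weights, so an over-sampled subject cannot dominate.

Graphs: nodes are the 18 body parts; weights are Pearson correlations
between mean response-field rows; negative correlations are removed, then
the lowest 5% of the remaining positive weights (computed over unique
undirected edges; ties with the cutoff are removed). Metrics use the
field-standard weighted conventions:

* degree `k_i = sum_j w_ij`;
* clustering from geometric-mean triangle intensities,
  `C_i = 2 t_i / (k_i (k_i - 1))` with the **binary** neighbour count in
  the denominator — a weighted degree there would make the coefficient
  unbounded (and negative for `k < 1`), so the bounded convention from the
  weighted-network literature is used, and per-node values are reported
  rather than a network average;
* shortest paths over lengths `1/w` by Dijkstra with Brandes-style counting
  of distinct minimal paths (ties at relative tolerance `1e-12`);
* betweenness normalised over unordered pairs,
  `b_i = \sum \rho_{hj}(i)/\rho_{hj} / ((n-1)(n-2))`, so a 3-node path's
  middle node scores 0.5;
* modularity `Q = 1/l \sum_{ij} (w_{ij} - k_i k_j / l)\,\delta(m_i, m_j)`
  with `l` the total weight counted over both directions (resolution 1).

Louvain module detection is run with seeded restarts; each restart permutes
the node processing order and additionally polishes a refined random
partition with greedy single-node moves, because the plain greedy sweep is
order-dependent and can stall one move short of the optimum on small
graphs. The reported `Q` is always a direct evaluation of the modularity
formula on the returned partition, independent of the search. Exhaustive
brute-force references (full path enumeration, all set partitions) ship in
the package and pin every metric down on graphs of up to 6 nodes.

## Statistics

* **Somatotopy gradients** — per subject and ROI, coordinates are rigidly
  rotated about the ROI centroid (determinant +1, no reflection) so the
  vector from the leg-group centroid (toes/ankle/knee centres) to the
  face-group centroid (lip/jaw/tongue) points along +y; the chosen quantity
  (centre index or size) is regressed on the rotated vertical coordinate,
  and per-subject slopes are tested against zero across subjects. The
  headline p-value is one-sided (slope > 0) per the directional hypothesis;
  the two-sided value is also reported.
* **Design-bias test** — per selected vertex, non-centre distances are
  split by whether the part was cued in the same run-part as the vertex's
  centre, and the pooled groups are compared by Welch t-test. Note that a
  homunculus-ordered ground truth is *not* null for this test: the run
  split itself follows the body layout, so group compositions differ.
  Calibration is therefore checked under run-independent random distances.
* **Head motion** — per cue, absolute first differences of the six rigid
  parameters are summed over volumes starting within 3 s of onset;
  rotations are converted to arc displacement at a 50 mm radius (the common
  framewise-displacement convention; the source protocol reports mm without
  stating its rotation handling). Per condition, a Welch t-test compares
  that condition's event scores with all other events pooled.
* **Map correlations** — Pearson over vertices non-zero in both maps with
  `df = N - 2`.

## The synthetic generator: what it emulates and what it does not

`make_somatotopic_ground_truth()` lays vertices on a flattened strip per
ROI and subject; preferred parts progress 1→18 along the strip with
optional jitter, every part is guaranteed a centre in every ROI, and true
distances grow with homunculus distance at an ROI-specific slope. The
default slopes (2.0 for M1/S1, 1.2 for SMA/Insula with a small-to-large
gradient along the strip, 1.0 PMd, 0.8 iPC/sPC, 0.5 PMv) encode the
qualitative regime the analysis expects — small response fields in primary
sensorimotor cortex, the largest in ventral premotor cortex — with
plausible sizes (M1 ≈ 1.2, PMv ≈ 5.5 on the FWHM scale). Timeseries are
generated by the package's own forward model plus iid Gaussian noise;
`calibrate_noise_sd()` bisects the noise level so the *fitted* median R²
(including overfitting inflation) matches a target, default 0.15 — the
realistic single-vertex regime.

What the generator does **not** emulate: cortical geometry and
vertex-to-vertex spatial correlation, physiological (non-white, AR)
noise spectra, HRF variability across vertices, preprocessing artifacts and
motion coupling. Passing tests therefore demonstrate correctness of the
estimator and pipeline under the model's own assumptions, not robustness
to everything real 7T data contains.

Problem sizes used by the verification suite — 512 vertices (2 subjects ×
8 ROIs × 32) for recovery, 2000 pure-noise vertices for calibration, 100
random ≤6-node graphs for the brute-force battery — keep a full run in the
minutes range on one CPU while leaving Monte-Carlo error well below the
asserted margins.

## Known limitations

* Distances beyond ~6 are reported at the bound; they are not estimable
  because the corresponding weights are below numerical noise.
* The F-test df convention is conservative (see above); absolute p-values
  should be read as bounds, and cross-study comparisons should use the same
  convention.
* The conventional model's continuous centre and width make its sizes
  systematically larger than non-rigid sizes whenever a response field
  contains non-adjacent parts — it must widen the Gaussian to span them.
* Louvain restarts make module recovery reproducible but not provably
  optimal beyond the exhaustively-checked small-graph regime.
* The design-bias and head-motion tests pool events/vertices, treating them
  as exchangeable; hierarchical structure (subjects) is not modelled there.
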