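# nrprf: non-rigid population response fields for motor-cortex fMRI

`nrprf` models how small neuronal populations in human motor cortices
respond to the movement of many different body parts. Conventional
population receptive/response field (pRF) modelling slides a Gaussian
tuning curve along a *fixed* feature axis (visual field position, auditory
frequency, or a homunculus ordering of body parts). That presumes the
ordering of features is known in advance — which for whole-body motor
control it is not. The non-rigid pRF model inverts the construction: the
Gaussian response field is held fixed (centre 0, sd 1) and the position of
every body part inside it is fitted.

For each cortical surface vertex with percent-signal-change timeseries
`y(t)`, the model is

    g_i   = exp(-dx_i^2 / 2),          dx_i in [0, 10],  i = 1..18
    r(t)  = sum_i s(x_i, t) * g_i      (s = binary task design matrix)
    p(t)  = (r * h)(t)                 (h = canonical double-gamma HRF)
    y(t)  = beta * p(t) + e

The fitted distances `dx` give, per vertex:

* **pRF centre** — the body part with minimal distance (ties: floor of the
  mean tied index), the population's preferred body part;
* **pRF size** — the proximity-weighted number of body parts inside the
  half-width-at-half-maximum window of the field
  (`FWHM = 2 * sqrt(2 log 2) ≈ 2.355`), roughly "how many body parts this
  population responds to";
* the full 18-element **proximity profile** `(10 - dx) / 10`.

Downstream, the package averages proximity profiles per region of interest
(ROI) and preferred body part into **mean body-part response fields**,
correlates those into weighted **body-part graphs**, and computes weighted
degree (connectivity), Onnela clustering, betweenness centrality,
characteristic path lengths and Louvain modules per body part — plus
somatotopy-gradient statistics on rotated flattened coordinates, a
task-design bias test, per-cue head-motion scoring, FDR vertex selection,
and the 18-condition task schedule / design-matrix / HRF machinery itself.
A synthetic-data generator produces somatotopic ground-truth maps and
forward-modelled noisy timeseries so the entire pipeline is testable
without scanner data.

Because the Gaussian weights sweep the full positive orthant while the
amplitude is free, the non-rigid model's prediction set is exactly a signed
linear cone of the convolved design; `nrprf` exploits this to fit each
vertex *globally* by sign-constrained least squares (see the methods
vignette, `vignettes/nonrigid-prf.Rmd`).

## Worked example

```r
library(nrprf)

# the 18-part whole-body protocol: 9 cues per part, 2 run-parts x 2 runs
# (237 + 191 volumes at TR 2.1 s), 3 s boxcars, canonical HRF
proto <- whole_body_protocol(seed = 1)
ncol(proto$design$s)
#> [1] 856

# a vertex that prefers the ring finger (part 9), with its homunculus
# neighbours nearby in the response field
dx_true <- pmin(1.2 * abs(1:18 - 9), 10)
y <- 1.5 * predict_timeseries(nonrigid_field(dx_true), proto$design,
                              proto$hrf)
fit <- nrprf(y, proto$design, proto$hrf)
fit
#> Non-rigid pRF fit
#>   centre: 9 (body part ring_finger)   size: 1.177
#>   beta: 1.5   R2: 1.0000   F: 1.203e+32 (p = 0)
```

The centre is recovered exactly and the size of ~1.18 says a single body
part dominates this response field. A full pipeline run on synthetic data:

```r
truth <- make_somatotopic_ground_truth(n_vertices = 32, subjects = 1:2,
                                       seed = 2)
Y <- simulate_vertex_timeseries(truth, proto$design, proto$hrf,
                                target_r2 = 0.15, seed = 3)
fits <- fit_vertices(Y, proto$design, proto$hrf,
                     vertex_info = truth[, c("subject", "roi", "vertex_id",
                                             "x", "y", "area")])
recovery_report(truth, fits)$overall
#>     n center_accuracy ...
#> 1 512       0.9355469 ...

mu <- mean_body_part_prf(fits, "M1")    # 18 x 18 mean response field
g  <- body_graph(mu)                    # thresholded body-part graph
graph_metrics(g, seed = 1)              # degree, clustering, betweenness,
                                        # path length, Louvain module
gradient_test(fits, "center")           # somatotopy gradients per ROI
```

At noise calibrated to the realistic regime (median fitted R² ≈ 0.15),
centre recovery stays ≈ 94% — far above the 1/18 ≈ 5.6% chance level.

A thin command-line wrapper is installed at `inst/cli/nrprf` with
subcommands `simulate`, `fit`, `aggregate`, `graph`, `stats`, `report`
(see `?cli_main`).

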