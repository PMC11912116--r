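# nmrflow

Compound identification and quantification in mixture NMR spectra by
minimum-cost network flow.

Given a library of individual compound peak lists (chemical-shift
positions in ppm with intensity weights, 1–3 axes) and a target mixture
spectrum — either a picked peak list or raw gridded intensities — the
package fits **all library compounds simultaneously** by solving a
linear network-flow program. No peak picking of the mixture spectrum is
required: grid cells, just like picked peaks, are simply weighted nodes.

## The model

A source produces the target's total weight `V_Y = Σ_j w_j`. Each
library compound `k` is a hub that splits its source flow `f_{s→k}`
across its peaks in the fixed proportions `p_i = v_i / V_{X_k}`, so
compounds are always fitted whole. A compound peak at `x_i` may send
flow to any target node `y_j` within the assignment radius `r` at unit
cost `d(x_i, y_j)` (scaled Euclidean distance; default axis scales
`(1, 0.1)` put `r` on the ¹H ppm scale for ¹H,¹³C HSQC data). Target
nodes are sinks with capacity `w_j`; unassigned production is absorbed
at a penalty `c_∅ ≫ r`. Among flows satisfying

* conservation: `Σ_k f_{s→k} + f_{s→∅} = V_Y`,
* capacity: inflow at each target node `≤ w_j`,
* proportionality: each peak of `k` carries exactly `p_i · f_{s→k}`,

the solver returns one of minimal total cost. Flows are quantitative:
`α_k = f_{s→k} / V_{X_k}` scales compound `k`'s library spectrum to its
assigned intensity, and with library spectra acquired at a known
concentration `c°_k`, the predicted mixture concentration is
`c_k = α_k · c°_k`. A compound is called contained when its flow
fraction `f_{s→k} / V_Y` reaches a detection threshold `ϑ`.

Three variants: single-pass simultaneous optimization (`solve_mcf()`;
setups A on grids, D on peak lists), independent per-compound fits
(`solve_independent()`; setup B — a diagnostic that exposes the
over-detection simultaneous fits avoid), and incremental assignment
(`solve_incremental()`; setup C — solves a ladder of increasing radii
and reserves flow once assigned, stabilizing the fit at large `r`).

## Worked example

Twelve synthetic library compounds, four of them mixed at 2.5–5.5 mM,
with realistic shift and intensity noise:

```r
library(nmrflow)

lib <- make_library(12, peaks_per_compound = c(3, 8), seed = 2024)
truth <- setNames(c(4.0, 2.5, 5.5, 3.0), lib$ids[c(2, 5, 7, 11)])
mix <- make_mixture_peaks(lib, mixture_spec(
  truth, shift_noise_sd = c(0.01, 0.1), weight_noise_cv = 0.1, seed = 7))

net <- build_flow_network(lib, mix$target, r = 0.08)
fit <- solve_mcf(net)
fit
#> <flow_result (setup A): 12 compounds, assigned 13.7052 of 14.4879 (94.6%), absorbed 0.782694
#>   total cost 782694, 4 compounds with positive flow>
```

94.6% of the target intensity is explained by four compounds; the rest
(one noisy peak pattern that no whole compound accounts for) is
absorbed, which dominates the total cost through the `c_∅ = 10⁶`
penalty. Containment calls and concentration estimates:

```r
calls <- detect(fit, total_weight(mix$target), threshold = 0.005)
subset(calls, detected)
#>    compound_id flow_fraction detected
#> 2     cmpd_002     0.2512882     TRUE
#> 5     cmpd_005     0.1556630     TRUE
#> 7     cmpd_007     0.3383137     TRUE
#> 11    cmpd_011     0.2007112     TRUE

subset(quantify(fit, lib), predicted_mM > 0)
#>    compound_id source_flow      alpha predicted_mM
#> 2     cmpd_002    3.640647 0.12135489     3.640647
#> 5     cmpd_005    2.255236 0.07517454     2.255236
#> 7     cmpd_007    4.901468 0.16338226     4.901468
#> 11    cmpd_011    2.907891 0.09692971     2.907891

classification_metrics(calls, names(truth), lib)[c("precision", "recall", "f1")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $f1
#> [1] 1
```

Exactly the four mixed compounds are detected, and the estimates (3.64,
2.26, 4.90, 2.91 mM) track the true 4.0, 2.5, 5.5, 3.0 mM to within the
injected 10% intensity noise plus the flow lost to shifted peaks.

Gridded targets run through the same pipeline after conversion
(`bin_grid()`, `grid_to_peaks()`), or end to end from files via
`run_fit()`/`run_config()`. A command-line interface with `fit`,
`simulate`, `scan` and `convert` subcommands is installed at
`system.file("exec", "nmrflow", package = "nmrflow")`.

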