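---
title: "Mixture deconvolution of NMR spectra by minimum-cost network flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture deconvolution of NMR spectra by minimum-cost network flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(nmrflow)
```

## The reconstruction problem

To a first approximation, the NMR spectrum of a mixture is the sum of the
spectra of its constituents. Given a library of individual compound
spectra — here, peak lists: sets of chemical-shift positions $x_i$ (ppm,
one to three axes) with intensity weights $v_i$ — and a target mixture
spectrum $Y$, mixture reconstruction asks for nonnegative concentration
factors $\alpha_k$ such that $\bigcup_k \alpha_k X_k$ approximates $Y$.
Two practical obstacles shape the method: peaks shift between acquisitions
(matrix effects, pH, temperature), so positions only match approximately;
and the target is often available only as raw gridded intensities, not as
a picked peak list.

`nmrflow` treats both target representations identically: a grid cell,
just like a picked peak, is simply a node carrying a weight. Matching is
formulated as a minimum-cost flow on a directed network:

* a **source** produces the target's total weight
  $V_Y = \sum_j w_j$;
* one **hub** per library compound $k$ receives source flow
  $f_{s \to k}$ and splits it across the compound's peak nodes in the
  fixed proportions $p_i = v_i / V_{X_k}$, so a compound is always fitted
  as a whole, in its library proportions;
* a **compound peak** $i$ may send flow to every target node $j$ within
  the assignment radius $r$ (closed boundary, $d(x_i, y_j) \le r$), at
  unit cost equal to the chemical-shift distance $d(x_i, y_j)$;
* each **target node** $j$ is a sink of capacity $w_j$;
* an **absorption sink** of unlimited capacity takes any production that
  cannot (or should not) be assigned, at a fixed unit cost
  $c_\varnothing > r$.

A feasible flow conserves production, respects sink capacities, and
splits hub flow proportionally. Among the feasible flows, the method
selects one of minimal total cost
$\sum_{i \to j} d(x_i, y_j)\, f_{i \to j} + c_\varnothing f_{s \to
\varnothing}$, a linear program. Assigned flows are fully quantitative:
$\alpha_k = f_{s \to k} / V_{X_k}$ is the scale at which compound $k$'s
library spectrum accounts for its assigned intensity, and with library
spectra acquired at a known concentration $c^\circ_k$ the predicted
mixture concentration is $c_k = \alpha_k c^\circ_k$. A compound is called
*contained* when its flow fraction $f_{s \to k} / V_Y$ reaches a
detection threshold $\vartheta$.

Because proportional splitting admits no partial compounds, a compound
with even one peak that has no target node within $r$ can carry no flow
at all. This strictness is deliberate (tolerance toward missing peaks
would require a penalty model that is out of scope) and is applied as a
presolve reduction before the linear program is assembled.

## Optimization variants

Three solver variants expose different bias/robustness trade-offs:

* **Simultaneous, single pass** (`solve_mcf()`; setup A on grid targets,
  D on peak lists): all compounds compete in one program. Competition
  prevents the over-detection that independent fits are prone to, but at
  large $r$ the preference for maximal assigned volume can displace flow
  to the wrong compound.
* **Independent** (`solve_independent()`; setup B): one single-compound
  program per library entry, each against the full target capacities.
  Useful as a diagnostic; two compounds covering the same intensity can
  both receive full flow, and summed flow fractions may exceed 1 —
  deliberately left uncapped so the over-detection mode is visible.
* **Incremental** (`solve_incremental()`; setup C): solves a ladder of
  radii $r_1 < r_2 < \dots < r_{\max}$, and after each step *reserves*
  all assigned flow — assigned capacity is removed and never displaced
  later. Close matches are locked in before distant ones become
  admissible, which stabilizes the fit at large radii. Within each step
  the full proportionality constraint holds; across steps only the
  cumulative flow balance is maintained. Each step's production is set to
  the residual total capacity so the absorption term cannot distort the
  step optimum. The default ladder climbs in steps of 0.01 from 0.01 to
  $r_{\max}$.

## Parameters that matter

* **Assignment radius `r`** (in scaled ppm, see the metric below): the
  tolerance to peak position shifts, plus — for grid targets — roughly
  the half-width of a peak, since the full spatial extension of a peak
  must be reachable. Detection tolerates partial peak coverage
  ($r \approx 0.05$ works well), quantification needs the full extension
  ($r \approx 0.15$); with the incremental variant the choice matters
  much less.
* **Detection threshold `theta`** (dimensionless fraction of $V_Y$):
  0.005–0.01 suits mixtures of well-concentrated compounds; dilute
  components need smaller values, at the price of precision. A practical
  calibration is to raise $\vartheta$ until a blank spectrum with the
  same noise character yields zero detections (`detect()` on a fit of a
  blank grid).
* **Absorption cost `c_absorption`** (default $10^6$): orders of
  magnitude above $r$, so optimal flows maximize assigned volume and
  absorption is a last resort. Setting it on the order of $r$ instead
  makes the method prefer precise fits even at the cost of absorbing
  flow; the parameter is exposed for that regime.
* **Metric axis scales** (default `c(1, 0.1)` for 1H,13C HSQC):
  distances are $\sqrt{\sum_a (s_a \Delta_a)^2}$, so with the default the
  radius lives on the 1H ppm scale and 0.05–0.15 ppm brackets typical 1H
  peak widths (0.03–0.09 ppm); 13C differences are compressed tenfold to
  reflect the larger spread of 13C shifts. The scales are configurable;
  the appropriate compression depends on the experiment.
* **Grid floor** (default 0): grid cells at or below the floor are
  dropped at conversion; 0 removes the negative baseline artifacts that
  must never become sink capacity, and raising the floor to about three
  times the baseline noise standard deviation excludes noise cells — the
  convention used throughout the package's benchmarks.

## Synthetic study conditions

All tests and the acceptance script run on seeded synthetic data; no
external spectra are required. The generators emulate the structure of
2D 1H,13C HSQC data:

* `make_library()` draws peak positions uniformly (1H 0–10 ppm, 13C
  0–160 ppm by default) with gamma-distributed weights normalized so a
  compound's total weight equals its acquisition concentration (unit
  sensitivity; 30 mM by default). An optional minimum pairwise scaled
  separation supports the well-separated regime where recovery must be
  exact.
* `make_mixture_peaks()` forms the scaled union of the contained
  compounds' peaks, perturbing positions with zero-mean Gaussian shift
  noise and weights with unit-mean lognormal noise of a given CV.
* `render_grid()` deposits each peak as a per-axis-discretized Gaussian
  (truncated at 4 SD and renormalized, so the cell sum equals the peak
  weight exactly) and adds Gaussian baseline noise.

The benchmark used by `scripts/acceptance.R` and the heavier tests: 10
compounds with 3–8 peaks, true concentrations 2–6 mM against 30 mM
library spectra, shift noise 0.01 ppm on the 1H-scaled metric (per-axis
0.01/0.1 ppm), 10% weight CV, rendered at 256×256 with peak widths
0.03/0.3 ppm and baseline noise SD 0.002, floored at three sigma
(0.006). The detection benchmark scales the published task down to a
40-compound library with 12 contained compounds at 40–60 mM. A
501-compound library at full grid resolution is well within the
method's reach but not exercised by the default test run.

What these conditions do *not* emulate: t1-noise streaks, solvent
ridges, phase and baseline distortion, correlated shift drifts
(pH-dependent, compound-specific), peak-shape deviations from a
Gaussian, and library/target acquisition mismatches. Passing the
synthetic benchmarks therefore demonstrates the correctness of the
optimization and the calibration machinery, not performance on real
plasma-grade samples.

## Numerical choices

* The linear program is solved by a dense primal simplex (compiled,
  `src/simplex.cpp`) on a reduced formulation: because hub→peak splits
  are fixed, one volume variable per compound plus one variable per
  admissible peak→target arc suffice. The reduction also yields a
  natural feasible starting basis (absorption + capacity slacks + one
  degenerate arc per peak row), so no phase-1 is needed.
* Degenerate vertices are common in assignment problems; the solver uses
  Dantzig pricing with a Bland fallback after long degenerate stalls,
  re-certifies optimality against a fresh factorization before
  terminating, and recomputes the final basic solution from the original
  data. Feasibility residuals (conservation, capacity, proportionality)
  are attached to every result and tested to $10^{-8} V_Y$.
* Ties between equal-cost optima are accepted as solved; results are
  deterministic for identical inputs (fixed variable ordering) but only
  objective value and feasibility are contractual, not the particular
  optimal vertex.
* The neighborhood boundary is closed ($d \le r$) so that a radius equal
  to an exact peak distance includes the match.
* Grid binning sum-pools blocks (total intensity conserved exactly,
  coordinates averaged); when an axis length is not divisible, the last
  bin absorbs the remainder cells.
* Peak-list and grid files are written with the shortest decimal
  representation that parses back to the identical double, making file
  round trips exact.

## Known limitations

* No tolerance for missing peaks: one absent peak excludes the whole
  compound. This is the dominant failure mode for weak compounds on
  floored grids, where a weak peak may fall entirely below the noise
  floor.
* The incremental variant's advantage materializes when single-pass
  fits suffer displacement (dense, overlapping libraries at large
  radii). On sparse benchmarks with nothing to displace it ties with
  the single-pass fit, and its greedy early reservation can cost a few
  percent of accuracy — the bias toward few-peak compounds that comes
  with reservation semantics.
* Quantification on floored grids is biased slightly low, since peak
  tails below the floor are unreachable intensity.
* Peak shapes carry no cost information; a grid target represents shape
  only implicitly through many nodes.
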