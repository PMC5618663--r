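---
title: "Modelling RSFP photoswitching kinetics and switching fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RSFP photoswitching kinetics and switching fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfpfit)
```

## The problem

Reversibly switchable fluorescent proteins (RSFPs) can be toggled between a
fluorescent (on) and a dark (off) state with light. Negative switchers such
as the rsGreen family are driven off by the same cyan light that excites
their fluorescence and back on by violet light. Their usefulness for
RESOLFT, pcSOFI and related imaging depends on three properties this
package quantifies: molecular brightness, off-switching speed and contrast,
and resistance to *switching fatigue* — the progressive loss of recoverable
on-state fluorescence over hundreds of switching cycles.

Three observations anchor the kinetic analysis. First, a single
off-switching decay is not mono-exponential: it needs at least two
exponential components. Second, switching slows down over repeated cycles.
Third, the off-state baseline *rises* during the experiment before falling
again. All three are parsimoniously explained by two interconverting
emissive species: a fast-switching species A that dominates initially, and
a slow-switching species B with incomplete off-switching that accumulates
through light-driven A→B conversion and is eventually photodestroyed.

## The models

### Within one cycle: two-species off-switching

During the off half-cycle of cycle $n$, fluorescence follows

$$F_n(t) = a_n\left[(1-f_A)e^{-k_A t} + f_A\right] +
           b_n\left[(1-f_B)e^{-k_B t} + f_B\right] + c,$$

with shared kinetics across all cycles: rates $k_A > k_B > 0$ (the ordering
is an identifiability convention, enforced structurally in the fit via
$k_B = k_A\,\sigma(u)$), residual on-fractions $0 \le f_A \le f_B < 1$, and
a constant background $c \ge 0$. Each species relaxes mono-exponentially to
its own plateau; $f_B > 0$ encodes that B never switches fully dark, which
is what couples B's abundance to the baseline. Whether the residual
fraction is a fluorescence fraction or a population fraction cannot be
distinguished at the ensemble level; here it is defined as the residual
*fluorescence* fraction of species B. By default $f_A = 0$ (A switches off
completely) but it can be freed (`fit_f_A = TRUE`).

`fit_switching()` estimates the shared parameters from all off half-cycles
jointly by **variable projection**: for any candidate nonlinear parameter
set, the per-cycle amplitudes $(a_n, b_n) \ge 0$ are the exact solution of
a 2-variable non-negative linear least-squares problem (solved by active-set
enumeration, vectorised over cycles). A 500-cycle experiment therefore
requires a nonlinear search over only 4–5 parameters instead of more than
1000. Least squares is unweighted; this choice is recorded in every fit
report. The outer optimisation alternates bounded quasi-Newton passes with
Nelder–Mead polish until the objective stalls (relative function tolerance
$10^{-10}$, at most 500 outer iterations per pass, all recorded in the
`fit` element), because the profiled surface has long curved valleys in
which a single quasi-Newton run stops prematurely. Initialisation uses
mono-exponential fits of the first cycle (A dominates, seeds $k_A$) and the
last cycle (B dominates, seeds $k_B$).

Model order (one vs. two species) is compared per cycle by a small-sample
corrected information criterion on `fit_single_cycle()`'s profiled fits.
Residual sums of squares are floored at the numerical-noise level so that
two models which both fit to machine precision compare by parameter count
rather than by the logarithm of rounding noise.

### Across cycles: interconversion and photodestruction

The cycle index $n$ is the population clock (all rates per cycle,
dimensionless), matching how the per-cycle amplitudes are observed. With
light-driven conversion $k_{AB}$ and per-species destruction $k_{dA}$
(elsewhere written $k_{OA}$), $k_{dB}$:

$$\frac{da}{dn} = -(k_{AB}+k_{dA})\,a, \qquad
  \frac{db}{dn} = k_{AB}\,a - k_{dB}\,b,$$

with the closed form (for $\alpha = k_{AB}+k_{dA} \ne k_{dB}$)

$$a(n) = a_0 e^{-\alpha n}, \qquad
  b(n) = b_0 e^{-k_{dB} n} + a_0 k_{AB}
  \frac{e^{-k_{dB} n} - e^{-\alpha n}}{\alpha - k_{dB}}.$$

When $|\alpha - k_{dB}| < 10^{-9}$ the analytic limit
$a_0 k_{AB}\, n\, e^{-\alpha n}$ replaces the cancellation-prone quotient.
B→A back-conversion is excluded from the default model — the rise-then-fall
of B needs none — but a $k_{BA}$ extension is available, handled by
eigen-decomposition of the 2×2 rate matrix. For $b_0 = 0$ the B population
peaks at $n^* = \ln(\alpha/k_{dB})/(\alpha-k_{dB})$, a useful closed-form
check. `fit_population_dynamics()` fits the closed form to the per-cycle
amplitudes by non-negative least squares, initialised by log-linear
regressions on $a_n$ and on the tail of $b_n$.

### Fatigue, baseline and stabilization metrics

`fatigue_metrics()` reports, per cycle, the maximally on-switched frame and
the maximally off-switched frame, both scaled to the initial on-state
fluorescence, their ratio (on/off contrast), and the number of elapsed
cycles until the on-level halves (linear interpolation). The baseline
trajectory should track $f_B\, b(n) + c$ — the residual fluorescence of
accumulated B — which is the model's explanation for rising baselines
without invoking a separate non-switching species.

Faster off-switching limits the photon dose absorbed per off half-cycle.
`expected_stabilization_from_speed()` uses the dose proxy
$D(k) = (1-f)(1-e^{-kT})/k + fT$ (the time-integral of the on population
over an off half-cycle of duration $T$) to predict how much of an observed
destruction-rate reduction is attributable to speed alone;
`observed_stabilization()` reports the actually fitted fold change
$k_{dA,\mathrm{free}}/k_{dA,\mathrm{fusion}}$ and the residual intrinsic
factor. Similarly, `decompose_rate_enhancement()` splits an off-rate
increase into the part explained by increased absorption (the apparent
extinction coefficient at the measurement pH, which already contains the
pKa shift) and an intrinsic remainder.

## Spectroscopy

The spectroscopic pipeline computes every derived column of the
characterisation table from measured inputs:

* `fit_pka()` — four-parameter sigmoid
  $A_{min} + (A_{max}-A_{min})/(1+10^{h(pK_a-pH)})$; the pKa is the
  inflection point. The slope coefficient $h$ is fitted (initialised at 1)
  rather than fixed, since nothing constrains it a priori. Flat or
  saturated titrations return a flagged failure instead of an extrapolated
  midpoint.
* `extinction_wards()` — the concentration-cancelling ratio form of the
  denatured-chromophore reference method. The reference extinction
  coefficient is an explicit argument, not a hard-coded constant.
* `extrapolate_eon()` — Henderson–Hasselbalch correction
  $\varepsilon_{on} = \varepsilon_{7.4}(1+10^{pK_a-7.4})$.
* `relative_quantum_yield()` — ratio method against a reference (default
  0.60); warns outside the optically thin regime and for yields above 1.
* `molecular_brightness()` — $\varepsilon_{7.4}\Phi_{FL}$ scaled to 100 for
  the reference construct.

All reported percents and scaled brightness values are rounded
half-away-from-zero to integers, and percent changes between scaled
brightness values are computed on the integer-scaled values — the single
rounding convention that reproduces the published table and percent
statements exactly. Extinction coefficients are carried internally in
L·mol⁻¹·cm⁻¹ and rendered in units of 10³ only in reports.

```{r table}
spectro_table(rsgreen_profiles())[, c("name", "pKa", "phi_fl",
                                      "eon_1e3", "brightness")]
compare_constructs(rsgreen_profiles())[, 1:6]
```

One number deserves a note: for the EGFP row the extrapolation gives
$52\times10^3 \times (1+10^{5.9-7.4}) = 53.6\times10^3$, which rounds to 54
rather than the tabulated literature value of 53; EGFP's entries are
literature-cited rather than products of this pipeline, so the packaged
checks assert only the four rsGreen constructs.

## The synthetic-data generator

`simulate_switching()` generates experiments with exactly the statistical
structure the fitting stages assume, from a mandatory seed (one seeded
generator per invocation; the caller's RNG stream is saved and restored).
Its defaults encode the emulated study conditions:

* **Protocols.** `protocol_hela(500)`: 25 violet on-switching periods then
  25 cyan off-switching periods of 100 ms each, 500 cycles.
  `protocol_colony()`: one cycle of 20 on / 40 off / 20 on periods of 30 s.
  Frames are exposed at the start of each period, so the first off-frame of
  a cycle still sits at the fully on-switched level.
* **On-switching** is modelled as complete and instantaneous at each violet
  half-cycle: the emulated experiments always on-switch to saturation
  before reading the on level, and per-cycle recovery is complete. A finite
  on-rate is available as a knob (`on_rate`), default off.
* **Population evolution** is applied once per cycle — the cycle index is
  the clock, matching the per-cycle amplitude observations; within-cycle
  destruction is not separately modelled.
* **Kinetics defaults** (`default_truth()`): $k_A = 10$ s⁻¹,
  $k_B = 1.2$ s⁻¹, $f_A = 0$, $f_B = 0.15$, $c = 0.02$. Both species
  essentially complete their off-switching within the 2.5 s off half-cycle
  ($k_A T = 25$, $k_B T = 3$), as in the high-power experiments emulated —
  this matters, because a slow species that never approaches its plateau
  within the half-cycle would leave $f_B$ ill-determined in *any* fit.
* **Population defaults**: $k_{AB} = 0.004$, $k_{dA} = 0.002$,
  $k_{dB} = 0.003$ per cycle, $a_0 = 1$, $b_0 = 0.1$: A decays to ~5% of
  its initial amplitude over 500 cycles and B peaks near cycle 230 — the
  characteristic rise-then-fall.
* **Noise**: shot noise as Poisson resampling at 2000 photons per intensity
  unit plus Gaussian read noise of 0.01 — an EM-CCD approximation giving a
  ~2% coefficient of variation at the initial on level. `shot_scale = 0`
  disables shot noise.
* **Thermal recovery** (`simulate_recovery()`): 10 min sampled every 30 s,
  relaxing as $F_\infty - (F_\infty - F_0)e^{-k_{th}t}$.
* **Colony images**: non-overlapping disks (overlap only if explicitly
  allowed) with log-normal brightness scales on a uniform background;
  row-major, 0-based pixel convention; no optical PSF, no camera gain
  registers, no per-molecule stochasticity — ensemble rates only.

What passing tests on these data do **not** show: robustness to cell
motion, uneven illumination, focus drift, autofluorescence or touching
colonies, none of which the generator emulates (and the extraction stage
deliberately performs no tracking, flat-fielding or watershed splitting).

```{r pipeline}
ex <- simulate_switching(protocol_hela(100), default_truth(seed = 7))
fit <- fit_switching(ex)
coef(fit)
pop <- fit_population_dynamics(fit)
coef(pop)
```

## Trace extraction

`segment_objects()` thresholds a reference frame (Otsu by default, or a
fixed value — the original thresholding choice is not prescribed, so both
are provided), labels 8-connected components and drops objects below
`min_area`. Otsu's between-class criterion is unreliable when foreground
covers only a few percent of the image or spans a wide brightness range;
for synthetic colony layouts with log-normal brightness the fixed mode is
the dependable choice. `extract_traces()` averages pixels per object and
frame, subtracts the per-frame median of unlabelled pixels (configurable
off; zero when no background pixels exist), and normalises the population
mean trace to the *last frame of the first on-illumination block* — the
point of complete on-switching, stored explicitly as
`normalization_frame_index` so reports are auditable. Per-object maxima
(`object_brightness()`) are taken over raw, un-normalised traces because
they feed cross-construct brightness comparisons.

## Numerical choices and degenerate inputs

* Optimiser tolerances: relative function tolerance $10^{-10}$ and 500
  outer iterations for the global fit (recorded in the result); $10^{-12}$
  for the population fit; sigmoid and recovery fits use Levenberg–
  Marquardt with up to 500 iterations.
* $k_A > k_B$ is structural ($k_B = k_A\sigma(u)$), preventing label
  switching; $k_B/k_A > 0.95$ triggers a rank-deficiency warning.
* $\alpha \approx k_{dB}$ uses the analytic limit (threshold $10^{-9}$).
* Flat recovery traces return $k_{th} = 0$ exactly; decreasing traces are
  flagged as positive-switcher behaviour but still fitted.
* A blank segmentation image yields an empty map with a warning, not an
  error; extraction from an empty map is an error.
* Non-finite parameters anywhere are rejected by validation before any
  computation.

## Problem sizes used in the packaged checks

The packaged test-suite exercises the full 500-cycle study design for the
headline parameter-recovery checks and the rise-then-fall trajectory
checks; replicate-based checks (noisy kinetic recovery across seeds,
fold-stabilization recovery across 20 paired simulations) use 100–150
cycles per replicate, which the recovery analyses show is already
comfortably identifying. Colony-image checks use 64–128 px frames with
4–12 disks.

## Known limitations

* Per-cycle destruction and interconversion are lumped; whether loss also
  occurs during on half-cycles is not separable in this design.
* Whether violet on-switching light contributes to A→B interconversion is
  likewise not separable; the generator attributes interconversion to the
  cycle as a whole.
* The dose proxy for expected stabilization ignores any intensity
  dependence of the destruction quantum yield.
* Unweighted least squares throughout; shot-noise-aware weighting would
  change cycle weighting slightly at low signal.
* The closed-form population model assumes first-order, time-invariant
  per-cycle rates; saturation or power drift would violate it.
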