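# rsfpfit

Quantitative analysis of reversibly switchable fluorescent protein (RSFP)
photoswitching, built for the rsGreen family and its binder (nanobody)
fusions but applicable to any negative switcher.

Negative-switching RSFPs are driven to a dark state by the same cyan light
that excites them and recovered with violet light. Their value for
RESOLFT/pcSOFI-type imaging hinges on brightness, switching speed and
contrast, and resistance to *switching fatigue* over hundreds of cycles.
Three experimental signatures — bi-exponential off-switching decays,
switching that slows over repeated cycles, and a baseline that rises before
falling — are jointly explained by two interconverting emissive species:

* within the off half-cycle of cycle *n*:
  `F_n(t) = a_n[(1-f_A)e^(-k_A t) + f_A] + b_n[(1-f_B)e^(-k_B t) + f_B] + c`,
  with the kinetics `(k_A, k_B, f_A, f_B, c)` **shared across all cycles**
  and per-cycle non-negative amplitudes `(a_n, b_n)`;
* across cycles, light-driven conversion A→B plus per-species
  photodestruction: `da/dn = -(k_AB + k_dA) a`,
  `db/dn = k_AB a - k_dB b`, solved in closed form.

The global fit uses variable projection (amplitudes solved per cycle by
exact 2-variable non-negative least squares inside the nonlinear search),
so a 500-cycle, 12 500-point experiment reduces to a 4-parameter
optimisation. The package also computes the spectroscopic characterisation
table (sigmoid pKa fits, Ward's-method extinction coefficients,
Henderson–Hasselbalch extrapolation to the deprotonated chromophore,
relative quantum yields, scaled molecular brightness), extracts traces from
image stacks (threshold → 8-connected components → background-subtracted
mean traces normalised at complete on-switching), reports fatigue/contrast
metrics, and ships a fully seeded synthetic-data generator that emulates
the colony-plate and live-cell experiments so every stage is testable
without microscope data.

## Worked example

```r
library(rsfpfit)

# Spectroscopy: derived columns from measured inputs (pKa, QY, eps at pH 7.4)
spectro_table(rsgreen_profiles())[, c("name", "pKa", "phi_fl",
                                      "eon_1e3", "brightness")]
#>                name pKa phi_fl eon_1e3 brightness
#> 1              EGFP 5.9   0.60      54        104
#> 2          rsGreen1 6.2   0.46      69        100
#> 3 rsGreen1-Enhancer 4.4   0.47      78        123
#> 4          rsGreenF 6.8   0.42      65         73
#> 5 rsGreenF-Enhancer 5.6   0.37      72         88

compare_constructs(rsgreen_profiles())[, 1:6]
#>       free            fusion eon_change_pct brightness_change_pct
#> 1 rsGreen1 rsGreen1-Enhancer             13                    23
#> 2 rsGreenF rsGreenF-Enhancer             11                    21
#>   ecoli_change_pct hela_change_pct
#> 1              -43             -31
#> 2              -39             -36

# Synthetic 100-cycle live-cell experiment and the two fits
ex  <- simulate_switching(protocol_hela(100), default_truth(seed = 7))
fit <- fit_switching(ex)            # shared two-species kinetics
round(coef(fit), 4)
#>    k_A    k_B    f_A    f_B      c
#> 9.8770 1.1617 0.0000 0.1452 0.0198   # truth: 10, 1.2, 0, 0.15, 0.02

pop <- fit_population_dynamics(fit)  # interconversion + destruction
round(coef(pop), 5)
#>    k_AB    k_dA    k_dB      a0      b0
#> 0.00387 0.00214 0.00273 1.00308 0.09835   # truth: 0.004 0.002 0.003 1 0.1

fatigue_metrics(ex)
#> Fatigue report over 100 cycles:
#>   on-level: 1 -> 0.801; baseline: 0.0255 -> 0.0662 (peak 0.0683 at cycle 83)
#>   cycles to half on-level: not reached
```

The brightness columns read: the Enhancer fusions are 23%/21% brighter per
molecule, yet 43%/39% dimmer in colonies and 31%/36% dimmer in HeLa cells —
in-vitro gains do not transfer in situ. The kinetic fits recover the
generating truth to a few percent at realistic noise; the rising baseline
(0.026 → 0.068 before declining) is the accumulating slow species B, whose
incomplete off-switching (`f_B = 0.15`) leaks fluorescence into the
off-state frames.

`run_pipeline()` chains simulate → extract → fit-switching →
fit-populations → fatigue from a config list or YAML/JSON file and writes a
CSV/JSON artifact bundle plus a manifest with config/input hashes. All file
dialects are UTF-8 comma-separated CSV with a header row and '.' decimal.

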