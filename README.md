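# cosolvency

Solubility modelling and dissolution thermodynamics for drugs in binary
cosolvent + water mixtures.

Poorly water-soluble drugs are often formulated by blending water with a
miscible cosolvent such as polyethylene glycol 400 (PEG-400).  Given a grid
of equilibrium mole-fraction solubilities `x_e(m, T)` over cosolvent mass
fraction `m` and absolute temperature `T`, this package computes the full
standard analysis:

* **Ideal solubility & activity coefficients** — from fusion calorimetry,
  `ln x_idl = -ΔH_fus(T_fus - T)/(R T_fus T) + (ΔC_p/R)[(T_fus - T)/T + ln(T/T_fus)]`,
  and `γ_i = x_idl / x_e`.
* **Hansen solubility parameters** — `δ = √(δ_d² + δ_p² + δ_h²)` for pure
  substances and the linear blend rule `δ_mix = α δ₁ + (1 − α) δ₂`.
* **Apparent dissolution thermodynamics** — OLS of `ln x_e` on
  `(1/T − 1/T_hm)` at the mean harmonic temperature `T_hm = n/Σ(1/T_i)`,
  giving `Δ_sol_H⁰ = −R·slope`, `Δ_sol_G⁰ = −R·T_hm·intercept`,
  `Δ_sol_S⁰ = (Δ_sol_H⁰ − Δ_sol_G⁰)/T_hm`, plus enthalpy–entropy
  compensation analysis.
* **Five cosolvency correlation models** — van't Hoff, Apelblat,
  Yalkowsky-Roseman, Jouyban-Acree and Jouyban-Acree-van't Hoff, each
  validated by percent root-mean-square relative deviation (%RMSD) per
  composition.
* **Synthetic surfaces** — a seeded generator of van't Hoff-consistent
  solubility grids with multiplicative lognormal noise, for
  parameter-recovery and robustness studies.

The package ships the emtricitabine / PEG-400 / water dataset (11
compositions × 5 temperatures, 298.2–318.2 K) as `ect_solubility()`,
with the matching fusion constants as `ect_fusion()`.

## Worked example

```r
library(cosolvency)

ect <- ect_solubility()
thermo_profile(ect)
#> Apparent dissolution thermodynamics at T_hm = 308.04 K
#>    m dH (kJ/mol) dG (kJ/mol) dS (J/mol/K)     R2
#>  0.0       14.54       11.91         8.54 0.9993
#>  0.1       13.67       11.33         7.63 0.9948
#>  ...
#>  1.0       12.05        5.34        21.77 0.9970
```

Dissolution is endothermic everywhere (`ΔH⁰ > 0`), and both the enthalpic
and free-energy barriers shrink as the PEG-400 fraction grows — the
thermodynamic signature of cosolvent solubilisation.  `Δ_sol_G⁰` falls from
11.91 kJ/mol in pure water to 5.34 kJ/mol in pure PEG-400.

```r
compare_models(ect)
#> Cosolvency model comparison (best first)
#>      model n_params overall %RMSD
#>   apelblat       33          0.40
#>   vanthoff       22          0.52
#>    jouyban        1          1.25
#>       javh        5          1.38
#>  yalkowsky        0          1.49
```

All five models correlate the surface to within ~1.5 %; the
three-parameter-per-composition Apelblat fit is tightest, while the pooled
one-parameter Jouyban-Acree model describes all 55 cells to 1.25 % — the
best accuracy-per-parameter.  A full report (ideal solubility, activity
coefficients, Hansen blend profile, thermodynamics, model ranking) comes
from:

```r
rep <- run_full_analysis(ect, ect_fusion(),
                         hsp = c(delta_cosolvent = 18.90,
                                 delta_antisolvent = 47.80))
write_report(rep, json = "report.json", text = "report.txt")
```

Synthetic data and parameter recovery:

```r
spec <- synthetic_spec(noise_cv = 0.011, seed = 7)   # study-like conditions
fit  <- fit_cosolvency(generate_surface(spec), "javh")
recovery_experiment(spec, n_replicates = 100, model = "javh")
```

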