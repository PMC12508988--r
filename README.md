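# helixfit

Thermal denaturation of a single-domain protein, monitored either by
circular dichroism (CD, as a normalized helicity degree) or by differential
scanning calorimetry (DSC, as a baseline-subtracted excess heat capacity),
is usually analyzed with models that ignore the solvent. `helixfit`
implements the Zimm–Bragg helix–coil model *with water*: hydrogen bonding
between the polypeptide and surrounding water molecules is summed into the
partition function, which renormalizes the helix stability weight and lets
a fit return the actual hydrogen-bonding energies — intramolecular
(N–H···C=O) and polypeptide–solvent — instead of only a melting temperature
and an enthalpy.

## Model

The transfer-matrix eigenvalues of the Zimm–Bragg chain are

λ₁,₂ = ½ [ 1 + s̃ ± √((1 − s̃)² + 4σ s̃) ],

and water renormalizes the stability weight to

s̃(T) = (1/Q) [ (A + (B − A)/q)⁻² − 1 ],  A = e^(−hβ), B = e^((h_ps−h)β),
β = 1/(R (T − t₀)),

with Q = 1/σ the entropic cost of intra-polymer hydrogen bonding, q = 16
the entropic cost of polymer–water bonding, and t₀ a glass-transition
reference temperature (all evaluation requires T > t₀). CD melts are fit
with the degree of helicity θ = (s̃+σ)/N · ∂lnZ/∂s̃ (finite-chain or
long-chain partition function); DSC thermograms are fit with the
per-residue heat capacity

C_V = −2Nh θ′ − 2Nh_ps X′ (1 − θ) + 2Nh_ps X θ′,
X = e^(h_ps β) / (q + e^(h_ps β) − 1),

the exact temperature derivative of the mean hydrogen-bonding energy
E = −2Nh θ − 2Nh_ps X (1 − θ). Free parameters: t₀ (K), h (J/mol),
h_ps (J/mol), Q (dimensionless); fits report percent standard errors, R²,
the derived T_m, and warning codes when any parameter error exceeds 50% or
R² falls below 0.5. See the methods vignette
(`vignettes/helixfit-methods.Rmd`) for derivations, numerical choices and
identifiability analysis.

## Worked example

Simulate a noisy CD melt at known parameters and fit it:

```r
library(helixfit)
truth <- zb_params(t0 = 200, h = 3000, hps = 2500, Q = 100, q = 16, N = 100)
spec <- synthetic_spec(truth, "cd_long", t_min = 280, t_max = 370,
                       n_points = 100, noise_sd = 0.01, seed = 42)
fit <- fit_curve(generate_curve(spec)$curve, fit_config("cd_long"))
print(fit)
#> Water-renormalized Zimm-Bragg fit (mode: cd_long)
#>   t0   =      135.031 K      (5.7e+03%)
#>   h    =      3974.89 J/mol  (4.1e+04%)
#>   hps  =      150.883 J/mol  (1.7e+07%)
#>   Q    =      128.036 1      (1.5e+02%)
#>   R^2 = 0.999443 on 100 points
#>   T_m = 331.3418 K
#>   warnings: PARAM_ERROR
```

The curve is reproduced almost perfectly (R² = 0.9994) and the melting
temperature is sharp (truth: 331.32 K), but the percent errors — and the
`PARAM_ERROR` warning — show that a single CD sigmoid cannot pin down all
four physical parameters: they trade off along a ridge. A DSC thermogram
of the same system is far more informative:

```r
peak <- max(heat_capacity(seq(280, 370, length.out = 100), truth, "long",
                          per_residue = TRUE))
dspec <- synthetic_spec(truth, "dsc", 280, 370, 100,
                        noise_sd = 0.02 * peak, seed = 42)
dfit <- fit_curve(generate_curve(dspec)$curve, fit_config("dsc", n_units = 100))
print(dfit)
#> Water-renormalized Zimm-Bragg fit (mode: dsc)
#>   t0   =        198.7 K      (0.67%)
#>   h    =      3047.57 J/mol  (2.5%)
#>   hps  =      2553.92 J/mol  (3.9%)
#>   Q    =      101.233 1      (4.7%)
#>   R^2 = 0.993797 on 100 points
#>   T_m = 331.2865 K
```

Here the peak position, height, width and tails recover t₀, h, h_ps and Q
to a few percent each (truth: 200 K, 3000 J/mol, 2500 J/mol, 100).

## Command line

```sh
HELIXFIT=$(Rscript -e 'cat(system.file("cli/helixfit", package = "helixfit"))')
Rscript "$HELIXFIT" simulate --kind cd_long --t0 200 --h 3000 --hps 2500 \
    --Q 100 --t-min 280 --t-max 370 --n-points 100 --noise 0.01 --seed 7 \
    --out curve.csv
Rscript "$HELIXFIT" fit-cd curve.csv --mode long --temp-unit K --out results/
Rscript "$HELIXFIT" fit-dsc dsc.csv --n-units 128 --temp-unit C --value-unit kcal
```

Input files are headerless two-column CSV/TXT/DAT (temperature, signal);
temperatures may be K or °C and DSC units J, kJ, cal or kcal per (mol K).
`fit-*` writes `results.json`, `results.csv`, a data-plus-fit plot
(`fit.png`) and a reproducibility manifest.

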