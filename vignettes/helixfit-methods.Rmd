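---
title: "Fitting protein melting curves with the water-renormalized Zimm-Bragg model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting protein melting curves with the water-renormalized Zimm-Bragg model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixfit)
```

## The model

The Zimm–Bragg description of the helix–coil transition assigns each of
the $N$ repeat units of a polypeptide a statistical weight of $1$ in the
coil state and $s$ in the helical (hydrogen-bonded) state, with a
nucleation penalty $\sigma$ at every helix–coil junction. The transfer
matrix of this chain has eigenvalues

$$\lambda_{1,2} = \tfrac12\left[1 + s \pm \sqrt{(1-s)^2 + 4\sigma s}\right],$$

the roots of $\lambda^2 - (s+1)\lambda + s(1-\sigma) = 0$. `helixfit`
implements the water-renormalized variant of this model: the hydrogen-bond
degrees of freedom of the surrounding water are summed out of the
partition function, which replaces $s$ by

$$\tilde s(T) = \frac{1}{Q}\left[\left(A + \frac{B - A}{q}\right)^{-2} - 1\right],
\qquad A = e^{-h\beta},\; B = e^{(h_{ps}-h)\beta},\;
\beta = \frac{1}{R\,(T - t_0)} .$$

Here $h$ is the intramolecular N–H···C=O hydrogen-bond energy, $h_{ps}$
the polypeptide–solvent hydrogen-bond energy, $Q = 1/\sigma$ the entropic
cost of intra-polymer bonding, and $q$ the entropic cost of
polymer–solvent bonding, fixed at $q = 16$ for water. The temperature
enters through the non-Arrhenius inverse temperature
$\beta = 1/(R(T-t_0))$, where $t_0$ is a glass-transition reference
temperature that every fit must place below the lowest observed
temperature.

A useful identity guides the implementation: the renormalization bracket
factors as

$$A + \frac{B-A}{q} = e^{-h\beta}\,\frac{q - 1 + e^{h_{ps}\beta}}{q},$$

whose solvent denominator is exactly the denominator of the solvent-bond
occupancy

$$X(T) = \frac{e^{h_{ps}\beta}}{q + e^{h_{ps}\beta} - 1} \in (0, 1].$$

Because the two expressions share this structure, the package evaluates
every Boltzmann factor through a single function of $(E, T, t_0)$ — the
exponent convention lives in one place. Printed forms of the occupancy
sometimes abbreviate the exponent as $h_{ps}/T$; dimensional consistency
(an energy in J/mol requires $R$) and the shared solvent denominator above
fix the convention used here, $h_{ps}\beta$ with the same non-Arrhenius
$\beta$ as the stability parameter. An internally inconsistent choice
would fail the package's thermodynamic-consistency test loudly, since the
heat capacity mixes derivatives of both functions.

### Partition function and order parameter

For a finite chain,

$$Z_N = \frac{(1-\lambda_2)\lambda_1^N + (\lambda_1-1)\lambda_2^N}
             {\lambda_1 - \lambda_2},$$

and for long chains $Z = \lambda_1^N$. As printed, the finite-chain form
gives $Z_1 = 1$ identically (the numerator collapses to
$\lambda_1-\lambda_2$); the package keeps this boundary convention and
documents the identity rather than replacing it by a single-unit
enumeration. The degree of helicity — the order parameter monitored by
CD — is

$$\theta = \frac{\tilde s + \sigma}{N}\,
           \frac{\partial \ln Z}{\partial \tilde s} \in [0, 1].$$

The prefactor grouping $(\tilde s + \sigma)/N$ is the one consistent with
the closed long-chain expression: substituting $Z=\lambda_1^N$ yields
$\theta = (\tilde s+\sigma)\,\lambda_1'/\lambda_1$, which reproduces the
standard long-chain helicity formula term by term.

### Energy and heat capacity

The mean hydrogen-bonding energy of the chain is

$$E(T) = -2Nh\,\theta - 2Nh_{ps}\,X\,(1-\theta),$$

two backbone bonds of energy $h$ per helical unit plus two solvent bonds
of energy $h_{ps}$, occupied with probability $X$, per coil unit. Its
exact temperature derivative is the excess heat capacity

$$C_V = -2Nh\,\frac{\partial\theta}{\partial T}
        - 2Nh_{ps}\frac{\partial X}{\partial T}(1-\theta)
        + 2Nh_{ps}X\frac{\partial\theta}{\partial T},$$

which is what DSC measures after native-baseline subtraction (with the
usual $C_V \approx C_P$ reading). A subtlety worth recording: the
derivative of the *conformational* log partition function with respect to
the effective inverse temperature,
$-\partial \ln Z/\partial \beta$, equals $E + 2Nh_{ps}X$ — the
$(\tilde s + 1/Q)$ and $(\tilde s + \sigma)$ factors cancel because
$\sigma = 1/Q$. The difference $2Nh_{ps}X$ is the solvent reservoir term
that tracing out the water removes from the bookkeeping; `internal_energy()`
returns the total $E$ above so that `heat_capacity()` is its exact
derivative, and the test suite checks both identities (the reservoir
relation against a finite difference of $\ln Z$, and $C_V$ against a
finite difference of $E$).

All $\theta$ and $X$ derivatives in $C_V$ are analytic closed forms
(`dX/dT = h_{ps} X(1-X)\,d\beta/dT`, and $d\theta/d\tilde s$ through first
and second derivatives of $\ln Z$); finite differences appear only as test
oracles.

## Parameters

| symbol | meaning | unit | fitted? | default start |
|---|---|---|---|---|
| $t_0$ | glass-transition reference temperature | K | yes | $\min(T) - 100$ |
| $h$ | intra-polypeptide H-bond energy | J/mol | yes | 4000 |
| $h_{ps}$ | polypeptide–solvent H-bond energy | J/mol | yes | 4500 |
| $Q$ | entropic cost of intra-polymer bonding ($\sigma = 1/Q$) | 1 | yes | data-driven (see below) |
| $q$ | entropic cost of polymer–solvent bonding | 1 | fixed | 16 (water) |
| $N$ | number of repeat units | 1 | input | — |

$N$ must be supplied for short-chain CD fits (the finite-chain $\theta$
depends on it) and for DSC fits, whose results are reported per repeat
unit. DSC fitting uses the long-chain order parameter inside $C_V$,
matching the long-chain thermograms of single-domain proteins the method
is intended for; `heat_capacity()` itself supports both chain-length
modes.

## Numerical evaluation

* **Log space everywhere.** $\ln Z$ is the canonical quantity;
  $\lambda_1^N$ is factored out of the finite-chain form so only
  $(\lambda_2/\lambda_1)^N < 1$ is ever exponentiated. No overflow occurs
  up to $N = 10^6$ and $|h|, |h_{ps}| \le 10^5$ J/mol at $T - t_0 \ge 1$ K.
  At such extremes $\tilde s$ itself exceeds double range; the observables
  then take a saturated all-helix branch ($\theta = 1$,
  $\partial\theta/\partial T = 0$) so every reported value stays finite.
* **Cancellation-free eigenvalue differences.** $1-\lambda_2$ and
  $\lambda_1-1$ suffer catastrophic cancellation for small $\sigma$; the
  rationalized forms $2\sigma s/(D \pm (s-1))$ (with
  $D^2-(s-1)^2 = 4\sigma s$) are exact there and bring the closed form
  within $10^{-14}$ of a compensated-arithmetic recurrence oracle.
* **Degenerate eigenvalues.** When
  $|\lambda_1-\lambda_2| < 10^{-10}\lambda_1$ the confluent limit
  $Z = \lambda^{N-1}(\lambda - N(\lambda-1))$ replaces the 0/0 form.
* **Melting temperature.** $\theta(T_m) = 1/2$ is located by bracketing
  bisection to $10^{-4}$ K after a 512-point scan of the search window; if
  cold and heat transitions both cross, the highest decreasing crossing is
  reported.

## Fitting

Least squares runs on a normalized internal space chosen to keep all four
coordinates of order 1–10 and to enforce the hard constraints by
construction: $\log(\min(T)-t_0)$ (so $t_0 < \min(T)$ always), $h$ and
$h_{ps}$ in kJ/mol, and $\log Q$ (so $Q \ge 1$, i.e. $\sigma \le 1$). The
optimizer is Levenberg–Marquardt (`minpack.lm`) with a numeric Jacobian,
a 1024-iteration cap and an evaluation budget of five times
`max_iterations`. Fitting in the raw physical space is available
(`normalized = FALSE`) and agrees with the normalized route to
$10^{-6}$ relative on well-conditioned problems — a regression test, not a
recommended path.

Two practical devices stabilize the search. First, because $Q$ enters
$\tilde s = (e^f - 1)/Q$ only as a scale, the default start sets
$Q = e^{f(T_{mid})} - 1$ at the empirical transition midpoint (half-range
crossing for CD, peak position for DSC), which centres the initial model
on the observed transition; a user-supplied initial $Q$ overrides this.
Second, if the first start fails to converge or leaves $R^2 < 0.5$, up to
five seeded log-normal jitters of the start are tried and the best
residual sum kept.

Uncertainties are percent standard errors from the residual-variance
scaled covariance $\hat\sigma^2 (J^\top J)^{-1}$ at the solution, mapped
to physical units by the delta method. Two warning codes mirror standard
practice: `PARAM_ERROR` when any percent error exceeds 50 (strictly), and
`LOW_R2` when $R^2$ falls below 0.5 (strictly). A fit that cannot
converge, or whose covariance is singular, raises an error inviting the
user to inspect the data and the initial values.

## The synthetic generator and what passing tests mean

`synthetic_spec()`/`generate_curve()` evaluate the forward model on a
uniform temperature grid and add homoscedastic Gaussian noise — the noise
model implicit in unweighted least squares. The package default fixture is
$t_0 = 200$ K, $h = 3000$ J/mol, $h_{ps} = 2500$ J/mol, $Q = 100$,
$q = 16$, $N = 100$ on 100 points over $[280, 370]$ K: a single sharp
heat-denaturation sigmoid with $T_m \approx 331.3$ K whose plateau, full
transition and coil tail all sit inside the grid. With $h_{ps} < h$ the
model has no cold-denaturation branch, matching the heat-denaturation
scope of the fitting modes. These values are package conventions chosen to
exercise a cooperative single-domain melt, not measurements of any
particular protein.

Synthetic curves are smooth, strictly gridded, homoscedastic and
model-generated; real CD and DSC data bring baseline curvature,
deconvolution and baseline-subtraction artifacts, heteroscedastic noise
and model misspecification. Recovery tests therefore demonstrate the
correctness and stability of the estimator under its own assumptions —
not the accuracy to be expected on laboratory data.

### Identifiability

The four free parameters act on the observable curve almost entirely
through $\tilde s(T)$ and $\sigma$, and over a typical 90 K window the
map $(t_0, h, h_{ps}, Q) \mapsto \tilde s(\cdot)$ is nearly rank-three:
in the transition region the solvent term is close to linear in $\beta$,
so $h$ and $h_{ps}$ trade off against each other and against $t_0$.
Linearized standard errors at realistic CD noise (sd 0.01 on a 0–1
helicity scale, 100 points) are of order 100% per parameter, and seeded
recovery experiments concentrate estimates on a curved ridge some tens of
percent long even though the fitted curves are visually perfect
($R^2 > 0.999$). This is a property of the model-plus-experiment
combination, not of the optimizer: restarts initialized at the ground
truth converge to residual sums *below* the truth's and still land on the
ridge. DSC is much better conditioned — the peak height, width, position
and tails of $C_V(T)$ pin all four parameters to a few percent at 2%-of-
peak noise. This asymmetry is the quantitative reason the reported percent
errors matter and why the 50% warning threshold is routinely relevant for
CD fits of small, smooth melts; fitting CD and DSC data of the same system
jointly is the natural remedy and a possible extension.

### Problem sizes in the shipped tests

The test suite evaluates the recurrence oracle on a $20 \times 20$
$(\tilde s, \sigma)$ grid up to $N = 50$; thermodynamic consistency on
200-point grids for five parameter sets; the finite-size limit at
$N = 10^5$ (where the residual $\theta$ gap is the genuine $O(1/(N\sigma))$
boundary correction, about $7 \times 10^{-5}$ for $\sigma = 10^{-2}$ —
finite-chain corrections decay algebraically, not exponentially); and
20-replicate recovery experiments per mode at 100 points each.

## Limitations

* Heat denaturation only: cold-denaturation DSC data are out of scope, and
  parameter regions with $h_{ps} > h$ (where a cold branch exists and
  $\tilde s$ can turn negative near $t_0$) are supported for forward
  evaluation but not targeted by the fitting modes.
* Single-domain, single-transition curves; multi-peak thermograms are not
  modelled.
* Solvents other than water only through the `q` override.
* CD input must already be deconvoluted and normalized to a 0–1 helicity
  degree, and DSC input must be native-baseline subtracted; the package
  validates but does not perform either preprocessing step.
* Plot export is static PNG; no interactive graphics.
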