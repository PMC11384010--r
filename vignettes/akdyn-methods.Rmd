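---
title: "Conformational dynamics and substrate binding in adenylate kinase: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational dynamics and substrate binding in adenylate kinase: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akdyn)
```

## Scope

Adenylate kinase (AK) catalyzes ATP + AMP &#8652; 2 ADP and couples its
chemistry to large-scale domain motions: the LID and NMP domains close over
the CORE domain to form the active site, and re-open to exchange and
reposition substrates. The package implements, on synthetic data, the full
analysis chain used to study how this open/closed equilibrium and substrate
binding jointly set the turnover of the enzyme, including the puzzling
activation of AMP-inhibited AK by sub-denaturing urea:

* a twelve-state conformational-kinetic reaction network and its
  steady-state/transient solvers (`model_core`);
* global chi-square fitting of turnover curves with profile-likelihood
  confidence intervals (`model_fitting`);
* classical assay analysis: initial velocities, product-inhibited reverse
  time courses, Michaelis-Menten and 1:1 isotherm fits (`assay_analysis`);
* photon-by-photon two-state maximum-likelihood hidden Markov analysis of
  single-molecule FRET bursts with burst search, corrections, Viterbi
  dwell decoding, recoloring and burst-variance validation (`smfret`);
* generators that emulate every input the chain consumes
  (`synthetic_data`), plus file formats and an end-to-end demo pipeline
  (`pipeline_io`).

## The kinetic model

Six ligation states — apoenzyme `E`, binary complexes `ET` (ATP) and `EM`
(AMP), inactive ternary complexes `ETMi` ("ATP first" binding order) and
`EMTi` ("AMP first"), and the active ternary complex `ETM` — each exist as
an open and a closed conformer, giving 12 states. The continuous-time
generator encodes:

* **Binding between open conformers only.** The closed active site is
  shielded from solvent, and substrate rearrangement requires the open
  form; the binding topology of the closed conformers is not observable
  from the fitted data, so the package declares open-only binding as its
  convention. Pseudo-first-order on-rates are `k_on [L]` with
  `k_on = 1e8 M^-1 s^-1` (diffusion-limited) for both ligands and
  `k_off = k_on Kd`. Steady-state turnover is insensitive to the absolute
  `k_on` as long as binding exchange is much faster than turnover, which
  holds by two orders of magnitude here.
* **Conformational exchange** `open <-> closed` in every ligation state at
  rates `k_open`, `k_close` with `K_C = k_close / k_open`.
* **Irreversible rearrangement** `ETMi(open) -> ETM(open)` at `k_r_T` and
  `EMTi(open) -> ETM(open)` at `k_r_M`. The reverse steps are not
  observable in the activity data and are omitted.
* **Catalysis** as an irreversible drain `ETM(closed) -> E(open)` at
  `k_cat`; the forward assay regenerates ATP and removes ADP, so product
  rebinding is not modeled. Because the enzyme is recycled, the generator
  conserves probability for any `k_cat`, and turnover is
  `k_cat * p(ETM closed)` at the stationary distribution.

Substrate inhibition by AMP emerges because `k_r_M << k_r_T`: at high AMP
the enzyme increasingly enters the slowly rearranging "AMP first" branch.

### Parameter values and the conformational-rate mapping

The wild-type constants are `k_cat = 3.1e3 s^-1`, `k_r_T = 4.2e3 s^-1`,
`k_r_M = 370 s^-1`, `Kd(ATP) = 50 uM`, and `Kd(AMP)` = 332 / 522 / 758 uM
at 0 / 0.4 / 0.8 M urea (`ak_params_wt()`). Conformational equilibria come
from the single-molecule measurements. Two mapping choices were genuinely
open and are resolved as follows:

* **Which measured `K_C` belongs to which species.** The measurements
  report `K_C` per condition, not per species: 0.16 for the apoprotein and
  with AMP alone, 1.28 with 1 mM ATP, 1.65 with 1 mM ATP + 5 mM AMP (0.85
  and 1.10 with 0.8 M urea). The package pairs each species with the
  condition in which it dominates: `E` and `EM` take 0.16; `ET` takes the
  ATP-only value; the three ternary species take the ATP+AMP value. The
  alternative (all ATP-bound species at the ATP-only value) changes
  steady-state velocities by under 10%.
* **Absolute rate scale.** Only `K_C` and the requirement that exchange be
  fast relative to catalysis matter for the steady state; the measurements
  put individual transitions in the tens-of-microseconds range, so the
  total relaxation `k_open + k_close` defaults to `6e4 s^-1` for every
  species. A scan over 3e4-1e5 s^-1 changes the reported velocities by
  well under 2%.

### Numerical solvers

The stationary state is obtained by a null-space linear solve (one balance
row replaced by normalization). An independent route propagates the linear
kinetic ODE by matrix exponentials, doubling the horizon by squaring the
propagator (with per-squaring column renormalization, since repeated
squaring amplifies any drift from stochasticity exponentially) until
`||dp/dt||_inf < 1e-10 s^-1`. The two routes agree to a relative 1e-6
across random models; the test suite checks 100 of them. Degenerate inputs
(e.g. unreachable states when rearrangement is switched off) make the
null-space solve singular by construction; it raises a diagnostic error
and the relaxation route remains usable.

## Global fitting and confidence intervals

`global_fit()` minimizes `sum(((v_model - v_obs)/sem)^2)` with the
urea-independent rate constants (`k_cat`, `k_r_T`, `k_r_M`) shared across
urea levels and the measured per-urea inputs (AMP affinity, conformational
rates) held fixed. Optimization runs in log-space (positivity by
construction) with a deterministic multi-start schedule: the seed guess
plus 15 starts drawn log-uniformly within two decades of it (RNG seed
1234), Nelder-Mead on each, best result retained. The chi-square
accumulates its terms in sorted order so the objective — and therefore the
optimum — is bit-identical under dataset reordering.

`profile_ci()` re-optimizes the remaining parameters on a grid of the
profiled one and reports the region where the reduced chi-square stays
within `1/dof` of its minimum, i.e. a raw chi-square increase of 1 (a
1-sigma interval; the original analysis does not state its threshold, so
this standard choice is declared). Profiles still below threshold at a
grid edge give open bounds — the package's analogue of reporting only a
lower bound for a catalytic rate far above the rate-limiting step — and an
essentially flat profile is flagged unidentifiable.

## Assay analysis

The reverse reaction (2 ADP -> ATP + AMP) is product-inhibited by AMP, so
product accumulation follows `[P](t) = (v0/eta)(1 - exp(-eta t))`; `v0` is
the true initial velocity and `eta` quantifies the curvature, with
`eta -> 0` recovering a straight line. `fit_product_inhibition()` fits this
form by nonlinear least squares and falls back to the linear fit with a
flag when the curvature is indistinguishable from zero over the observed
span. Forward-assay initial velocities are fitted linearly over the first
10% of the time course or 60 s, whichever is shorter, to minimize
inhibition bias; absorbance traces are converted with the NADH extinction
coefficient 6220 M^-1 cm^-1 at 1 cm path (a standard value; the assay
description does not state one). Michaelis-Menten and 1:1 isotherm fits
are weighted by supplied standard errors when present. Thermophoresis
titrations are fitted with a strict 1:1 isotherm plus amplitude/baseline
nuisance parameters (a Hill model was considered and rejected: the data
the generator emulates is 1:1 by construction, and the measured fold
changes are ratio-based and insensitive to this choice). Ligand depletion
is not corrected; a flag warns when the protein concentration exceeds
`Kd/10`.

## Photon-by-photon smFRET analysis

Bursts are located on the inter-photon interval trace: intervals are
smoothed with a 15-photon running average (the smoothed quantity is
declared to be the intervals; the acquisition description leaves it
ambiguous), stretches below the 5 us cut-off define bursts, and bursts
under 50 photons are discarded. Leakage is estimated from the apparent
FRET of donor-only bursts (`l = E_DO/(1-E_DO)`, donor-only selected at
raw stoichiometry > 0.85) and direct excitation from the stoichiometry of
acceptor-only bursts (`d = S_AO/(1-S_AO)`, selected at < 0.15); corrected
efficiencies subtract `l*DD + d*AA` from the acceptor channel and restore
the donor emission photon-conservingly to `(1+l)*DD`, so a static
distorted population inverts exactly. Double-labeled molecules are kept
at corrected stoichiometry 0.3-0.7. No detection-efficiency (gamma)
correction is applied — the emulated acquisition defines gamma = 1.

The hidden Markov model has two states (open/closed), state FRET
efficiencies as emission probabilities (acceptor photon: `E_s`; donor:
`1 - E_s`), and continuous-time switching: between photons the state
distribution is propagated with the analytic 2x2 matrix exponential.
Fitting maximizes the exact photon-by-photon likelihood numerically
(Nelder-Mead on logit-efficiency/log-rate coordinates, four deterministic
restarts); an expectation-maximization scheme over the same likelihood
was considered and set aside — for two states, direct maximization is
simpler, and the estimator is the identical MLE. Efficiencies can be
shared across condition sets (the conformer structures do not change with
conditions) or fixed to previously fitted values for perturbation series.
After fitting, the higher-efficiency state is labeled "closed" and
`K_C = k_close/k_open = P_closed/P_open`. A fit is flagged degenerate when
a single static state explains the photons nearly as well (likelihood
ratio below 10 units per set) or the efficiencies collapse.

Three validation tools mirror standard practice: Viterbi decoding with
dwell boundaries at midpoints between state-change photons; a recoloring
test that keeps observed photon times, redraws colors from the fitted
model and compares per-burst efficiency distributions by the two-sample
Kolmogorov-Smirnov statistic against the 95% envelope of
recolored-vs-recolored distances; and burst variance analysis comparing
the standard deviation of window efficiencies (default 100 photons)
with the binomial shot-noise expectation `sqrt(E(1-E)/n)`.

## What the generators emulate — and what they do not

Photon streams are generated as exponential-duration bursts (mean 1 ms, a
simple stand-in for diffusion transits) with constant in-burst Poisson
photon rates (200 kHz donor-excitation, matching bright transits;
acceptor-excitation interleaving at the same rate), Gillespie-sampled
two-state switching started from equilibrium, state-dependent photon
colors, and optional leakage, direct excitation, background, and
donor-/acceptor-only subpopulations. Not emulated: photophysics (blinking,
bleaching), diffusion through a three-dimensional focus (burst-duration
and intensity correlations), detector dead time, and lifetime information.
A green recovery test therefore establishes correctness of the estimators
under the model's own assumptions, not robustness to those artefacts.
Activity data are model curves with relative Gaussian noise; titrations
and reverse time courses follow their closed forms. All generators are
deterministic given their mandatory seed.

## Numerical choices

* Timestamps are integer nanoseconds; all rates are s^-1; units convert at
  the I/O boundary only.
* State ordering is fixed (ligation-major, open before closed), so
  generator matrices are reproducible bit-for-bit.
* Fit tolerances: Nelder-Mead relative tolerance 1e-10; HMM convergence is
  governed by the same criterion on the summed log-likelihood.
* `nls` fits use the `port` algorithm with positivity bounds and
  moment-based starting values (early slope/late plateau for the
  product-inhibition form, Lineweaver-Burk for Michaelis-Menten, the
  half-signal point for isotherms).

## Known limitations

* The steady-state model treats substrates as undepleted reservoirs and
  does not model the reverse reaction mechanistically (no ADP-bound
  species), so it applies to initial-velocity data only.
* Conformational rates enter as per-species constants; the measured
  AMP-dependence of the closing rate above ~0.5 mM AMP is not modeled.
  This is invisible at the steady-state observables reproduced here but
  would matter for transient predictions.
* The two-state HMM deliberately excludes >2-state models; data from
  multi-state processes should (and do, in the tests) fail the recoloring
  check rather than fit silently.
* At desk scale the burst generator cannot reproduce quantities that
  depend on the study's raw photon statistics (e.g. the measured 38%
  decrease of the product-inhibition curvature under urea, or the 1.3-fold
  opening-rate acceleration at 10 mM AMP); those are outside the package's
  validation targets.
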