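# akdyn

Adenylate kinase (AK) keeps cellular ATP levels balanced by catalyzing
ATP + AMP ⇌ 2 ADP. Its LID and NMP domains close over the CORE domain to
form the active site and re-open — on the tens-of-microseconds scale, two
orders of magnitude faster than turnover — to let the substrates
reposition. At high concentrations AMP inhibits the enzyme, and,
counter-intuitively, sub-denaturing urea *activates* the inhibited enzyme.
`akdyn` is an R package for analyzing this interplay between
conformational dynamics and substrate binding: it implements the kinetic
model, the fitting machinery, and the single-molecule FRET analysis chain
needed to study it, together with synthetic-data generators so every stage
runs and is tested without raw measurements.

## The model

The catalytically active ternary complex ETM can form by two binding
orders ("ATP first" via ET → ETMi, "AMP first" via EM → EMTi). The
misaligned ternary complexes must rearrange (rate `k_r`, possible only in
the open conformation) before phosphotransfer (`k_cat`, in the closed
conformation). Each of the six ligation states `E, ET, EM, ETMi, EMTi,
ETM` carries an open and a closed conformer with exchange rates `k_open`,
`k_close` (equilibrium coefficient `K_C = k_close/k_open = P_closed/P_open`),
giving a 12-state continuous-time network. Because the rearrangement in
the "AMP first" branch is slow (`k_r_M ≪ k_r_T`), flux entering that
branch at high AMP is partly trapped: substrate inhibition. Urea acts
through two measured inputs — it lowers AMP affinity (Kd 332 → 758 µM at
0.8 M urea) and shifts the ATP-bound conformers toward open (K_C 1.28 →
0.85 at 1 mM ATP) — and the model turns those two inputs into the observed
velocity changes.

Conformational populations and rates come from photon-by-photon hidden
Markov analysis of single-molecule FRET bursts of freely diffusing,
double-labeled enzyme: the two states (E_open ≈ 0.37, E_closed ≈ 0.72)
emit acceptor photons with probability equal to their FRET efficiency,
and the state distribution relaxes analytically between photons. The
package implements burst search, leakage/direct-excitation corrections,
stoichiometry selection, the maximum-likelihood HMM with globally shared
state efficiencies, Viterbi dwell decoding, recoloring and burst-variance
validation.

## Worked example

```r
library(akdyn)

## kinetic model: wild-type parameters at 0 and 0.8 M urea
p0 <- ak_params_wt(0); p8 <- ak_params_wt(0.8)
scan <- 10^seq(-5, log10(0.05), length.out = 60)
vc <- velocity_curve(p0, ak_conditions(atp = 1e-3, amp = 0), scan, "AMP")
max(vc$velocity_per_s)            # peak of the non-monotone AMP curve

cond <- ak_conditions(atp = 1e-3, amp = 5e-3)
steady_state_turnover(p8, cond)$turnover /
  steady_state_turnover(p0, cond)$turnover   # urea activation, inhibited regime

## smFRET twin: simulate bursts at K_C = 1.65 and recover it
bursts <- burst_search(simulate_photon_stream(fret_sim_config(
  n_bursts = 1000, k_open = 5000 / 2.65, k_close = 5000 * 1.65 / 2.65,
  seed = 42))$stream)
fit <- hmm_fit(bursts, fix_E = c(0.37, 0.72))
kc_from_model(fit)
```

This prints a maximum turnover of `403` s⁻¹ (reached near 493 µM AMP), a
`1.49`-fold velocity increase with the 0.8 M urea inputs at 5 mM AMP —
urea relieves the AMP inhibition — and a recovered `K_C = 1.66` from 943
detected bursts, matching the generating equilibrium within sampling
error. At 100 µM AMP the same swap *decreases* velocity: urea only
activates the inhibited enzyme.

`run_pipeline()` chains the full demonstration (simulate → burst search →
HMM fits → K_C table; simulate activity → global fit; velocity,
effect-isolation and rate-scan tables) into an output directory with
provenance. A thin CLI over the same functions is at
`inst/cli/akdyn.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's reference quantities from scratch — the fitted
AMP-affinity fold change under urea, the recovered dissociation constant,
the conformational equilibria recovered by the photon-by-photon fits at
three conditions, the globally shared state efficiencies, and the
urea/no-urea velocity ratio of the kinetic model — and writes them as a
JSON map of target ids to values.
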