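---
title: "Methods: stacked-foil activation analysis and Sc-47 production planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked-foil activation analysis and Sc-47 production planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sc47yield)
```

## The problem

Scandium-47 is a theranostic radionuclide (SPECT imaging via its 159 keV
line, beta-minus therapy) whose supply is limited. One production route is
proton irradiation of isotopically enriched Ti-48, where `48Ti(p,2p)47Sc`
competes with the coproduction of other scandium radioisotopes (Sc-46,
Sc-44m, Sc-44g, Sc-43) and V-48. Assessing the route requires two linked
computations, both implemented here:

* an **inverse pipeline** that turns stacked-foil activation measurements
  (gamma-ray peak counts of irradiated foils) into nuclear cross-sections
  with a defensible uncertainty budget, and
* a **forward pipeline** that turns fitted excitation functions into
  thick-target yields for candidate irradiation scenarios and follows the
  radionuclidic purity (RNP) of Sc-47 after the end of bombardment (EOB).

## Energy bookkeeping through the stack

In a stacked-foil irradiation each foil samples a different proton energy.
The package degrades the beam numerically through every layer (Kapton
vacuum window, air gap, Ti-48 deposits, Al backings, natNi monitors, Al
recoil catchers and degraders) by integrating `dE/dxi = -S(E)` over areal
density `xi`.

The mass stopping power `S` is the plain Bethe formula with the
heavy-projectile approximation for the maximum energy transfer, no shell or
Barkas corrections, and Bragg-rule additivity over elements for compounds.
Mean excitation energies are the standard values (Ti 233 eV, Al 166 eV,
Ni 311 eV, elemental values for the Kapton and air constituents). Above
10 MeV this is accurate to a few percent, which the tests verify against an
independently coded reference evaluation; below a 1 MeV floor the model is
refused rather than extrapolated. The per-foil energy uncertainty combines
the cyclotron extraction uncertainty (500 keV at stack entry) with
relativistic Bohr straggling of each traversed layer, in quadrature.

Numerics: RK4 steps on a fixed grid of 1 mg/cm^2 per step or 100 steps per
foil, whichever is finer. Halving the step moves a 500 um Al foil's exit
energy by well under 1 keV, so quadrature error is negligible against the
500 keV extraction term.

## From counts to cross-sections

For a counted peak, the EOB activity is

A_EOB = C (t_real/t_live) lambda / (3600 eps I_gamma e^(-lambda t_c) (1 - e^(-lambda t_real)))

with net counts `C`, cooling time `t_c`, acquisition real/live times,
detection efficiency `eps` and line intensity `I_gamma`. Decay during the
acquisition uses the real time; the live/real ratio is a multiplicative
dead-time correction, standard for the sub-10% dead times enforced by the
measurement-geometry invariant. Repeated counts of the same foil/product
combine by inverse-variance weighted mean after individual decay
correction.

Quantification lines come from a registry that flags interference-affected
lines as unusable: for Sc-46 only the 889 keV line is used (the 1120 keV
line suffers a Bi-214 background interference), and the Sc-44m 1157 keV
branch is excluded because it coincides with the strong Sc-44g line.

The proton flux is normalised per target position with the
`natNi(p,x)57Ni` monitor reaction: the recommended cross-section table is
interpolated with a shape-preserving Fritsch-Carlson cubic (the recommended
curve is smooth and a non-monotone spline could overshoot), its relative
uncertainty linearly; the roughly 1% of Ni-57 recoiling out of the monitor
is recovered from the downstream Al catcher and added back. The production
cross-section then follows from the activation equation, divided by the
target enrichment (0.9932) so results refer to a 100% Ti-48 target;
contributions from the residual 0.68% of other Ti isotopes are neglected.
The reported uncertainty is the quadrature sum of counting, efficiency,
line-intensity, monitor (about 4-5%, typically dominant) and areal-density
terms. The beam current is assumed constant over the 1-2 h runs.

## Excitation functions and thick-target yields

`fit_excitation()` builds a shape-preserving monotone-segment cubic through
the measured points plus a zero anchor at the reaction threshold, clipped
at zero and continued as a constant above the last point (flagged).
Thresholds are computed from atomic mass excesses for the lowest channel
emitting only nucleons and alphas (d/t/3He emission is weak): 11.69 MeV for
Sc-47 (p,2p), 22.56 for Sc-46, 14.17/14.45 for Sc-44g/Sc-44m, 24.08 for
Sc-43, 4.90 for V-48. They are overridable.

The thick-target EOB activity for a scenario (entry energy, irradiation
time, current) is the standard activation integral

A = (I/e) (N_A/M) (1 - e^(-lambda t_irr)) * integral of sigma(E)/S_m(E) dE

from the reaction threshold (the target is taken thick enough to degrade
below every threshold) up to the entry energy, by trapezoid on a 0.02 MeV
grid (halving the step changes results by far less than 0.1%). Products are
treated independently during irradiation - no isomer in-growth in the EOB
yields; feeding is applied only post-EOB. A scenario cell is left blank
(NA, never 0) when no measured point lies below the entry energy, mirroring
how yield tables distinguish "not produced in this window" from zero.

A known limitation: where the measured grid leaves a long gap above a
threshold (Sc-43 has no point between 24.1 and 35.5 MeV; cumulative Sc-46
none between 22.6 and 31.5 MeV), the interpolant bridges the gap roughly
linearly while real near-threshold cross-sections rise much more slowly, so
data-only yields for those products carry an upward bias of order tens of
percent. Merging external literature points via a user-supplied
cross-section CSV removes this at the user's discretion; the shipped
analysis is deliberately download-free.

## Post-EOB decay and radionuclidic purity

Activities evolve by exponential decay; Sc-44g additionally receives the
Bateman feeding term from the isomeric transition of Sc-44m,

A_g(t) = A_g(0) e^(-lambda_g t) + b (lambda_g/(lambda_g - lambda_m)) A_m(0) (e^(-lambda_m t) - e^(-lambda_g t)),

with the analytic limiting form when the decay constants coincide. The IT
branch `b` defaults to 0.988 (standard evaluated value, configurable); RNP
results move negligibly for a +-1% change. RNP is the Sc-47 activity
fraction among scandium isotopes only - V-48 is excluded because vanadium
is removed chemically with the titanium.

`time_to_rnp()` scans an hourly grid over a 5000 h horizon (generous
margin around the relevant 1000-2000 h scale) and refines the crossing by
bisection; an unreachable target (the 84 d Sc-46 outlives the 3.35 d Sc-47,
capping the achievable purity) reports `Inf`. `max_rnp()` refines the grid
optimum by local optimisation and flags monotone cases, where the purity is
still rising at the horizon because every impurity decays faster than
Sc-47.

## The synthetic campaign generator

`true_model()` fixes a complete ground truth: true excitation functions
(by default the fits through the shipped measured table, so synthetic
campaigns resemble the real experiment), a true flux of 100 nA, a
four-position stack spanning about 36 to 23 MeV (the Sc-47 peak region,
with every Ni monitor inside the recommended monitor-table range), a 1.5 h
irradiation, and an HPGe counting plan with efficiencies falling with line
energy, 2% dead time, early counts for the short-lived products and
overnight counts for the rest.

Poisson counting noise is the only sampled stochastic element;
areal-density and efficiency uncertainties enter the budget as fixed
systematic terms, mirroring the quadrature treatment of the analysis. Two
consequences for interpreting the tests: the noise-free campaign must
invert exactly (it does, to machine precision), and the pooled coverage of
the combined uncertainty is expected to be conservative (well above the
nominal 68%/99.7%), because the systematic components are included in the
reported uncertainty but never perturbed. What the generator does not
emulate: gamma-spectrum continua and peak-fitting errors, efficiency-curve
calibration errors correlated across lines, current fluctuations during the
run, and beam-energy misassignment; passing tests therefore validate the
inversion algebra and uncertainty bookkeeping, not those experimental
systematics.

## Problem sizes and determinism

The shipped analyses are desk-scale: 15-point excitation tables, 0.02 MeV
yield grids, hourly purity grids over 5000 h, and 500-replicate recovery
experiments on the four-foil synthetic stack. Every stochastic routine
takes an explicit seed and is bit-reproducible; the pipeline driver records
input hashes, the seed and all defaults in a provenance file, and rerunning
a config yields byte-identical outputs.
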