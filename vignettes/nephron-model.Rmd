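---
title: "A steady-state transport model of the human nephron: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A steady-state transport model of the human nephron: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nephrosim)
```

## The model

`nephrosim` solves steady-state water and solute transport along a single
superficial human nephron. Ten tubular segments are marched in flow order;
at every axial position a cell-based epithelium couples the lumen to the
interstitium. Fifteen transported solutes plus impermeant protein are
carried. The interstitial composition is an imposed boundary condition:
homogeneous in the cortex and varying linearly with corticomedullary depth
between printed anchor compositions at the cortico-medullary junction, the
outer–inner medullary boundary (0.5 cm) and the papillary tip (1.7 cm).

Key assumptions, all standard for steady-state nephron models of this
class:

* quasi-static coupling — the epithelium is at algebraic steady state at
  each axial position;
* the interstitium is imposed, not solved (no vascular exchange, no
  feedback from tubular transport onto the medullary gradient);
* SNGFR is prescribed (no tubuloglomerular feedback);
* cell volume is not a dynamic variable; the cell impermeant
  *concentration* serves as the volume-adjustment slack (fixed impermeant
  amount, adjustable effective volume);
* only the proximal tubule is compliant and flow-sensitive; downstream
  segments are rigid with flow-independent transport.

## The epithelial closure

Each axial position carries 35 unknowns: 15 cell and 15 lateral
log-concentrations, the cell and lateral potentials, the cell impermeant
concentration, the lateral interspace hydrostatic pressure, and the
luminal potential. The residuals per compartment are: water balance; the
five non-reacting solute balances (Na, K, Cl, urea, glucose); the four
buffer-group totals (the CO₂ group holds CO₂ + HCO₃⁻ + H₂CO₃); the four
pair equilibria plus the CO₂ hydration equilibrium; the acid-content
(proton) balance; and electroneutrality. The luminal potential is closed
by zero net transmembrane current out of the lumen, which keeps the
luminal fluid electroneutral along the axis.

Two design points deserve emphasis:

**CO₂ handling.** Dissolved CO₂ is held at equilibrium with H₂CO₃
(CO₂/H₂CO₃ = 329, the constant ratio of the interstitial anchor table;
equivalently an effective CO₂-group pKa of 6.16), and CO₂ counts in the
acid-content sum because CO₂ + H₂O = H₂CO₃. With this bookkeeping every
internal buffer reaction leaves the acid content invariant, and — given
the solute and group balances — **zero net current into each compartment
is an exact algebraic identity** of the residual set. Without the
hydration equilibrium the NHE3/H⁺-pump secretion cycle has no acid supply
(luminal H₂CO₃ at micromolar levels cannot carry the acid flux) and the
epithelial system has no physiological solution. Finite-rate (carbonic
anhydrase) kinetics are deliberately out of scope.

**Slack unknowns.** Imposing the flux balances alone leaves compartment
charge unpinned; imposing electroneutrality *instead of* the proton
balance breaks the current identity. Both hold simultaneously once each
compartment has its classical slack unknown — the cell impermeant
concentration and the lateral interspace pressure.

The system is solved by a damped quasi-Newton iteration in
log-concentration space with a lazily refreshed finite-difference
Jacobian, a trust-region step cap (2 log-units on concentrations, 30
mV/mmHg on potentials and pressure), and a Levenberg–Marquardt fallback
for near-singular Jacobians (the thermodynamic-equilibrium point is
genuinely rank-deficient: the pair-equilibrium rows become linearly
dependent on the species balances there). Residual rows are scaled by
fixed characteristic magnitudes built from boundary concentrations and
transporter densities per compartment; a state-dependent normalisation
would saturate at ±1 whenever all flux terms share a sign and destroy the
Newton geometry. Cold starts (one per segment) fall back to a homotopy
that ramps transporter densities from 10% to 100%.

## The axial march

The marched state is per-nephron flows: ωQ, ωQ·C_k for the five
non-reacting solutes, the four buffer-group totals, and the acid-content
total — thirteen components including pressure. This is algebraically
equivalent to the per-tubule coalescing equations and makes segment mass
audits telescope exactly. Species are recovered at each point by a
strictly monotone scalar pH solve. At the CNT→CCD junction the 10:1 merge
multiplies per-tubule flow by ten, preserves concentrations, conserves
buffer-group and proton totals, and re-equilibrates the pairs.

The luminal system is stiff: highly permeant species (CO₂, NH₃) relax to
quasi-equilibrium with the epithelium over length scales far shorter than
practical axial steps, especially at low distal flows (the stiffness
ratio approaches ~100 in the early IMCD). Explicit integrators overshoot
these modes catastrophically, so steps are taken with **TR-BDF2** — a
one-step, L-stable, second-order scheme — with each implicit stage solved
by simplified Newton using a finite-difference Jacobian of the luminal
right-hand side (refreshed every 25 steps and on step failure, when the
step is also halved recursively). Per-step flux integrals are accumulated
with the scheme's own quadrature weights, so the per-segment audit
`delivery_in − delivery_out = ∫ω J dx` closes to the implicit-stage
tolerance (observed ≲ 10⁻⁸ relative).

**Resolution.** The shipped default is 200 steps per segment. A
convergence study showed 48 versus 96 steps changes urine composition by
< 0.05% and 24 versus 48 by < 0.04%, so the test suite and the examples
run at 48 (96 for the halved-grid comparison); results at 48 and 200 are
indistinguishable at the 10⁻³ level.

**Compliant-tubule guard.** The linear compliance law r = r₀(1 + ν(P −
P₀)) has a collapse instability: falling pressure shrinks the radius,
which steepens the Poiseuille gradient as r⁻⁴, which drops pressure
further. The radius is therefore floored at 0.7 r₀ (a real tubule is
splinted by the surrounding parenchyma). The floor also caps a spurious
amplification of the torque response at raised SNGFR. Similarly, the
torque scale factor 1 + s(τ/τ₀ − 1) is floored at zero, since a negative
transporter density is unphysical.

**Torque scope.** Torque scaling multiplies transporter densities and
channel permeabilities on the cell membranes of proximal cells; the water
pathway and the paracellular route are not scaled. Scaling the water
permeability as well overdrives the flow response (fractional proximal
reabsorption then moves by more than 5 percentage points across a ±10%
SNGFR sweep).

## The reference parameter fixture

Printed constants are used verbatim: segment lengths and diameters, the
medullary axis (0.5 + 1.2 cm), SNGFR 100 nl/min, inflow pressure 21 mmHg,
viscosity 6.4×10⁻⁶ mmHg·s, compliance (r₀ 14 µm, P₀ 20 mmHg, ν 0.03),
microvillous geometry (l 2.5 µm, δ 0.15 µm), torque sensitivities (1.5
for S1–S2, 0.75 for S3), the interstitial anchor tables and the
loop-to-CCD ratio. The transport parameter set (areas, water and solute
permeabilities, reflection coefficients, transporter densities, cell
impermeants) descends from rodent-calibrated models whose values are not
published here, so the package ships a documented stand-in, chosen once
by segment-physiology sizing and calibrated so the baseline run lands in
physiological windows — mirroring the source study's own adjustment step
(SGLT2 lowered 25% on S1–S2; collecting-duct H⁺ pumps halved, both folded
into the shipped densities). Fixture choices a maintainer should know:

* the 1.7 cm proximal tubule is split 1.2 cm (S1–S2, cortical) + 0.5 cm
  (S3, reaching 0.18 cm into the outer medulla); no split is printed;
* the explicit HCO₃⁻/H₂CO₃ pair pKa is 3.646, fixed by requiring the
  cortical anchor composition (HCO₃⁻ 25 mM, H₂CO₃ 4.41×10⁻³ mM) to sit at
  pH 7.4; phosphate 6.8 (fixed by the titratable-acid formula), ammonia
  9.15, formate 3.75;
* proximal-tubule inflow equals the cortical interstitium minus protein,
  with a Donnan-style adjustment (Na −8.2, Cl +8.2 mM) restoring exact
  electroneutrality at unchanged osmolality — the unadjusted composition
  carries the charge that interstitial protein balanced, and a charged
  filtrate would amplify ~160-fold as water is reabsorbed;
* every solute receives a background permeability of 2×10⁻⁸ cm/s on every
  interface: no membrane is perfectly impermeable, and a solute with no
  pathway into a compartment would leave its concentration structurally
  undetermined (an exactly singular Jacobian);
* interstitial pressure is 5 mmHg; ammonia's cortical non-homogeneity is
  not represented;
* NKCC2 rate constants (not printed in the source) are a symmetric,
  detailed-balance-consistent set with K⁺ the high-affinity site; they
  are configuration, so published sets can be dropped in.

## What the baseline run shows — and does not show

With the reference fixture the model delivers, per kidney: urine flow
0.589 ml/min (physiological window 0.55–1.4), urine Na⁺ 72 mM, urea
328 mM, osmolality ≈ 704 mosm/kg; fractional Na⁺ excretion ≈ 0.3%; ≈ 99%
of filtered glucose reabsorbed with a ≈ 90/10 SGLT2/SGLT1 split; proximal
fractional Na⁺ reabsorption ≈ 71% that rises with SNGFR (sign and
approximate proportionality of glomerulotubular balance, carried almost
entirely by the torque mechanism — ablating it removes most of the
response). SGLT2 inhibition (90%, SNGFR ×0.97) produces osmotic diuresis,
natriuresis, kaliuresis and glucosuria; NKCC2 inhibition (80%, with the
medullary washout interstitium) produces diuresis and Na/K/Cl-uresis.

Known limitations of the fixture and structure:

* urinary K⁺ (≈ 108 mM; FE ≈ 16%) and urine pH (≈ 6.9) sit above the
  human reference points (FE ≈ 11%, pH ≈ 6.2): distal K⁺ secretion and
  acid excretion are only coarsely calibrated;
* at raised SNGFR the fixed-capacity distal segments capture most of the
  extra delivered NaCl, so urinary excretion *falls* as SNGFR rises —
  real distal segments saturate sooner; the proximal response itself is
  correct in sign and magnitude;
* luminal pressure at the papillary tip is slightly negative (≈ −10
  mmHg): with the printed distal diameters the merged collecting-duct
  flows imply a steeper Poiseuille drop than the source model reports;
  pressure feeds back on transport only weakly (ΔP terms are ~1% of the
  osmotic terms), so this is cosmetic rather than mechanistic;
* the printed-value discrepancy between the Table-1 proximal diameter
  (37 µm) and the compliance reference radius (14 µm) is resolved in
  favour of the compliance law for flow and torque, with the Table-1
  value retained in the geometry record.

Passing tests therefore demonstrate internal consistency (conservation to
tolerance, thermodynamic limits, oracle agreement), the printed
closed-form and arithmetic values, and the directional physiology of the
interventions — not quantitative agreement with human micropuncture data,
which does not exist, nor exact reproduction of the source model's urine
table, which would require its unpublished transport parameters.

## Numerical summary

| quantity | value |
|---|---|
| epithelial solver tolerance | 10⁻¹⁰ on scaled residuals |
| implicit-stage tolerance | 10⁻⁹ relative |
| axial scheme | TR-BDF2 (γ = 2 − √2), fixed step |
| default resolution | 200 steps/segment (tests: 48/96) |
| Jacobian refresh | lazy (quasi-Newton); every 25 axial steps |
| step-failure policy | Jacobian refresh, then recursive halving (≤ 5) |
| radius floor | 0.7 r₀ |
| torque-scale floor | 0 |
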