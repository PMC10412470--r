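---
title: "A reduced-order model of an aortically powered venous ejector pump for the Fontan circulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of an aortically powered venous ejector pump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vepsim)
```

## The problem

In a Fontan (total cavopulmonary connection, TCPC) circulation both vena
cavae drain directly into the pulmonary arteries. Without a subpulmonary
ventricle the systemic venous pressure must supply the entire transpulmonary
gradient, so the inferior vena cava (IVC) runs chronically elevated —
the root cause of late Fontan failure. A venous ejector pump (VEP) is a
passive implant that addresses this without an external power source: a
small graft off the ascending aorta feeds a nozzle whose high-velocity jet
discharges into the IVC pathway inside a mixing throat. Momentum exchange
between the jet and the slow venous stream raises the pressure along the
throat, which — with the downstream pulmonary pressure fixed — depresses
the throat *static* pressure and decompresses the IVC. An atrial-discharge
opening (a controlled fenestration from the device body to the atrium)
adds decompression and fail-safety at the cost of a right-to-left shunt.

`vepsim` reduces this device and its circulation to a lumped (0D) network.
It is a surrogate for 3D CFD: fast enough for design sweeps and property
testing, calibrated to published operating anchors, and honest about what
a 0D closure cannot represent (see *Limitations*).

## Network and closures

**Topology.** The IVC inflow enters the device port, passes the mixing
throat and leaves through the pulmonary port to a lumped pulmonary outlet
at fixed pressure. The SVC joins the pulmonary circulation downstream of
the device. The aortic graft connects the fixed aortic pressure to the
throat through the nozzle orifice; the atrial discharge connects the
throat to the fixed atrial pressure. Caval inflows are prescribed flows —
matching a rigid-walled, flow-driven venous compartment — and the two
pulmonary outlets are lumped into one 10 mmHg sink, since equal outlet
pressures make the left/right split irrelevant to device metrics.

**Orifice law.** Both shunts follow
$Q = \mathrm{sign}(\Delta P)\, C_d A \sqrt{2|\Delta P|/\rho}$.
The law is antisymmetric: the atrial discharge is an open hole and may
reverse (atrium into device) when the throat pressure falls below the
atrial pressure, which the solver permits (`q_ad < 0`); all other flows
are non-negative.

**Ejector closure.** A single constant-area momentum balance over the
throat:
$$\Delta P_{\mathrm{mix}} = \frac{\rho\,(Q_j v_j + Q_s v_s - Q_m v_m)}{A_T},$$
with the jet at nozzle velocity $v_j = Q_j/A_N$ and the secondary (venous)
stream referenced to the full throat area. Referencing the secondary to
the full area (rather than the nozzle-blocked annulus) is deliberate: it
makes the closure reduce *exactly* to a plain conduit when the jet is off,
so failure modes inherit no spurious suction. The mixed stream then
expands to the pulmonary port through a diffuser with pressure-recovery
efficiency $\eta$ (default 0.8, the classical conical-diffuser range; ideal
Bernoulli is used in the contraction direction). The throat static
pressure is the downstream pressure minus diffuser recovery minus
$\Delta P_{\mathrm{mix}}$, plus the calibrated caval pathway loss.

Two consequences of this closure are worth stating. First, a jet slower
than the mixed stream is *dragged* rather than driving, so the throat
pressure is not strictly monotone in jet flow in a small neighbourhood of
zero (a dip of order 0.01 mmHg here); monotone suction holds throughout
the jet-dominant regime in which the device actually operates. Second,
with the atrial discharge taken at the throat (where the device body
places it), strong suction at narrow throats can reverse the discharge.

**Pathway losses.** TCPC dissipation (caval impingement, junction
geometry) is lumped into one quadratic coefficient per caval pathway,
$\Delta P = K \cdot \tfrac12 \rho v^2$, with $v$ referenced to the 12 mm
caval port. The SVC pathway includes an optional interaction coefficient
(mmHg per L/min of jet-boosted pulmonary flow, default 0): the SVC rise
observed in 3D comes from caval flow impingement that a 0D network cannot
produce mechanistically, so it is exposed as a declared approximation and
left off by default.

**Oxygen model.** Atrial mass balance
$Q_P C_{PV} + Q_{AD} C_{AD} = \mathrm{CO}\cdot C_{sa}$ with the Fontan
venous-arterial relation $C_{sv} = 0.6\,C_{sa}$ and
$C_{AD} = C_{sv} + m\,(C_{sa} - C_{sv})$ gives the closed form
$$C_{sa} = \frac{Q_P\, C_{PV}}{\mathrm{CO} - (0.6 + 0.4\,m)\,Q_{AD}},$$
solved without iteration. The mixing coefficient $m$ — the arterial
fraction of the discharge stream — is closed by perfect throat mixing,
$m = Q_{AoG}/(Q_{AoG}+Q_{IVC})$, replacing the passive-scalar transport a
CFD solve would use; this is the canonical 0D closure and is reported
alongside the saturations so the approximation is visible. Saturations are
fractions internally and percent only at the reporting boundary. The
pulmonary-vein saturation defaults to 0.95, a deliberately conservative
ceiling. With CO defined as caval return plus graft steal and
$Q_P + Q_{AD} = \mathrm{CO}$, the balance above is conservative to
round-off for every solved state. A reversed discharge carries atrial
blood and produces no venous admixture, so $C_{sa} = C_{PV}$ in that case.

## Calibration

The model has two families of free coefficients, both pinned to published
anchors before any prediction is read:

* **Nozzle discharge coefficients.** The printed operating graft flows
  (0.315 L/min at 1.5 mm, 1.555 L/min at 3.0 mm) are inverted through the
  orifice law at the 55 mmHg aorta-to-pulmonary reference head, giving
  $C_d(1.5) \approx 0.80$ and $C_d(3.0) \approx 0.99$. Intermediate
  nozzles (2.0, 2.5 mm) use linear interpolation in diameter, clamped to
  the anchor range — a stated approximation, since only the end points are
  published. A calibration demanding $C_d \notin (0,1]$ is an error naming
  the offending anchor.
* **Pathway loss coefficients.** For each junction model the baseline
  (no-device) IVC and SVC pressures are matched exactly by the closed-form
  $K = (P_{fix} - P_{out}) / (\tfrac12\rho v^2)$ and verified by
  re-solving the baseline to within $10^{-3}$ mmHg. A fixture below the
  outlet pressure is rejected (negative loss impossible). The smoother
  patient-specific junctions calibrate to smaller $K$ than the idealized
  zero-offset model, as expected.
* The atrial-discharge coefficient has no published anchor; it is fixed a
  priori at 0.61, the classical sharp-edged-orifice value in the
  Reynolds-independent regime.

## Solver

All coupling is funnelled into a single scalar unknown, the throat static
pressure. The solver iterates the fixed-point map
graft flow → discharge flow → momentum balance with damping 0.7 until
successive iterates differ by less than $10^{-8}$ mmHg (the map's slope is
≈ 0.1 at the operating point, so convergence takes a few dozen
iterations), with a bracketing bisection fallback; it is deterministic,
initialization-independent, and agrees with an exhaustive $10^{-4}$ mmHg
grid search in the tests. Modes are constraint sets on the same system:
`BASELINE` removes the device entirely, `AOG_OCCLUSION` pins the jet flow
to zero with the discharge live, `FULL_FAILURE` pins both shunts to zero
with the device body in line. Mass residuals at the mixing and pulmonary
nodes are checked to $10^{-9}$ L/min in every mode.

## Scenario generation

`pediatric_scenario()` is the reference operating point: 2.1 L/min caval
return with a 60/40 IVC/SVC split, 65 mmHg aortic, 10 mmHg pulmonary and
5 mmHg atrial pressure, blood at 1060 kg/m³ and 0.0035 Pa·s.
`randomized_scenarios()` perturbs each continuous field independently and
uniformly within ±15% of these defaults for robustness and property
testing. Uniform (rather than Gaussian) perturbation keeps bounded
support, so the generated scenarios satisfy the physical invariants
without tail rejection; the ±15% band spans pediatric-to-young-adult
variation qualitatively. Generation is bit-reproducible under a fixed seed
and leaves the caller's RNG state untouched. What the generator emulates
is boundary-condition variability only — it does not emulate anatomy,
pulsatility, respiration or venous compliance, so passing property tests
demonstrate the network mathematics, not patient-level validity.

## Design sweep and selection criteria

The sweep enumerates 15 designs: four nozzle-study cases (1.5–3 mm at the
8/4 mm reference throat/discharge, where nozzle size dominates the graft
flow) plus the 2.5 mm nozzle crossed over throats 6–12 mm and discharges
4–6 mm, the shared case emitted once. Each design is solved in all four
modes and judged on four criteria with user-visible thresholds
(`criteria_config()`): aortic steal $Q_{AoG}/Q_S < 0.5$ (strict), arterial
saturation ≥ 80% in full assist, ≥ 80% under graft occlusion, and full
failure preserving the baseline (IVC within 0.6 mmHg — bracketing the
published full-failure rises of 0.18–0.59 mmHg — and no SVC elevation).
The `selected` flag marks the all-pass design with the largest full-assist
IVC drop.

In this 0D surrogate the selection logic reproduces the published
qualitative structure — the 3 mm nozzle fails the steal criterion, the
5–6 mm discharges desaturate under occlusion, the 2.5/12/4 mm design
passes all four — but the quantitative throat ranking differs: narrow
throats generate stronger suction in a momentum closure than in 3D (where
jet breakdown and wall losses intervene), so the surrogate's argmax
tie-break lands on the 2.0/8/4 mm design rather than 2.5/12/4. The
package treats the criteria logic as the testable contract and the
ranking as a known 0D-vs-3D divergence.

## Numerical choices and degenerate inputs

* Constraint violations in geometry are data (`validate_device()` returns
  a violation list), not exceptions; solvers reject invalid geometry.
* The mixing coefficient is undefined when both throat inflows vanish;
  callers short-circuit the oxygen model when the discharge carries no
  right-to-left flow.
* The oxygen closed form refuses unphysical flow sets (non-positive
  denominator) rather than returning saturations above the ceiling.
* Reports are written at full `%.17g` precision so the sweep CSV
  round-trips bit-for-bit; re-running a report on identical inputs yields
  byte-identical files.
* Problem sizes throughout (15 designs × 4 modes, 100-scenario property
  sweeps, a $10^{-4}$ mmHg grid oracle) were chosen as comfortable
  desk-scale settings for a scalar fixed-point model.

## Limitations

The surrogate inherits every 0D simplification: no jet breakdown length,
no wall shear or hemolysis/thrombogenicity indices, no caval impingement
mechanism (hence SVC pressure is flat across modes unless the interaction
coefficient is enabled), no pulsatility, respiration, compliance or
multi-scale closed-loop coupling, and patient-specific junctions enter
only through their calibrated baseline pressures. Interpolated discharge
coefficients for the 2.0/2.5 mm nozzles are an approximation, not
published ground truth. Conclusions that depend on these effects —
notably the throat-size ranking during assist — require 3D analysis; the
package's value is the calibrated, testable network around them.
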