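---
title: "Simulating the failing human ventricular wall in one dimension: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the failing human ventricular wall in one dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hfstrand` simulates electrical propagation in a one-dimensional transmural
strand of human ventricular myocardium — a computational stand-in for a
left-ventricular wedge preparation — and measures the repolarization,
calcium and conduction biomarkers through which heart-failure (HF)
remodeling is thought to create an arrhythmogenic substrate.  This vignette
is the package's account of the science it implements: the membrane models,
the remodeling profiles, the cable numerics, the biomarker definitions, and
the design choices made where the problem was genuinely open.

## The tissue model

The strand is a chain of nodes, one per cell, spaced `dx = 0.01` cm.  Wall
thickness 1.65 cm corresponds to the 165-cell transmural strand used for the
two-class experiments (82 endocardial + 83 epicardial cells); the
three-class strand is 170 cells (60 endocardial, 45 midmyocardial, 65
epicardial).  Membrane potential obeys the monodomain reaction–diffusion
equation with sealed ends,

$$\partial_t V = -\,i_{\mathrm{ion}}(y, V) + i_{\mathrm{stim}} +
  \kappa\,\partial_x\!\left(D(x)\,\partial_x V\right),$$

with currents expressed per unit membrane capacitance (µA/µF), `D` in
cm²/ms, and a dimensionless constant `κ` into which the surface-to-volume
ratio and specific capacitance are folded.  `κ` is calibrated once so that
the normal-coupling strand (`D = 0.0006` cm²/ms) conducts at 50 cm/s —
the experimental transmural velocity that `D` itself was chosen to
reproduce; the calibration run gave `κ = 1.0329`, i.e. the uncalibrated
model already conducted at 49.2 cm/s.  Note that the unit of `D` is cm²/ms:
printed values such as "0.0006 cm/ms" in the wedge-simulation literature
only balance dimensionally as cm²/ms, and with that reading the stated
50 cm/s is reproduced.

Intercellular uncoupling (connexin-43 loss) is modeled by reducing `D`
uniformly: `none` 0.0006, `mild` 0.00045, `normal-HF` 0.0003 (the two-fold
reduction measured in failing myocardium), `severe` 0.00025 cm²/ms.

## Membrane models

Three membrane formulations stand behind the node types:

* **GPB** — the Grandi–Pasqualini–Bers human ventricular myocyte
  (endocardial/epicardial variants differing in the transient outward
  current), with junctional-cleft, subsarcolemmal, cytosolic and SR
  compartments and a detailed Ca²⁺-buffering system.  Because the
  heart-failure profile rescales a late Na⁺ current that the base model
  lacks, the model is extended with a Maltsev/Undrovinas-style
  `I_NaL = G_NaL·mL³·hL·(V−E_Na)` (`τ_hL = 600` ms, `G_NaL = 0.0065`
  mS/µF), following the heart-failure lineage built on this model.
* **ORd** — the O'Hara–Rudy human ventricular myocyte with
  endocardial/midmyocardial/epicardial variants (the midmyocardial class has
  the intrinsically longest action potential) and CaMKII-dependent
  phosphorylation of Na⁺, Ca²⁺ and SR fluxes.
* **FIB** — the MacCannell "active" ventricular fibroblast: a time- and
  voltage-dependent K⁺ current, an inward-rectifier K⁺ current, a Na⁺/K⁺
  pump and a background Na⁺ current, on a 6.3-pF membrane.  Intracellular
  Na⁺/K⁺ are held at their published values, which makes the ≈ −49.6 mV
  rest a true equilibrium of the four-current membrane (our transcription
  equilibrates at −49.0 mV; letting the ion pools drift would carry the
  cell over hours to a much more negative pseudo-steady state, which is not
  the regime the strand experiments probe).

All three were transcribed from the published formulations of their
respective papers.  State vectors are explicit named registries
(`init_state()`), so traces and checkpoints are self-describing, and every
model exposes the same contract: a fixed-step advance of gates and
concentrations returning the total ionic current, plus a pure-derivative
entry point (`cell_rhs()`) for reference integrations with a stiff solver.

## Heart-failure remodeling

The homogeneous HF profile rescales, identically in every cell class:
`I_NaL` ×2.0 (GPB) / ×1.8 (ORd) with the same factor on its inactivation
time constant `τ_hL` (slower inactivation, not a rate scaling), `I_to`
×0.4, `I_K1` ×0.68, `I_NaK` ×0.9 / ×0.7, `I_Nab` ×0 (GPB only; the ORd
background Na⁺ current is unchanged), `I_Cab` ×1.53 (GPB), `I_NCX` ×1.75,
`J_SERCA` ×0.5, SR leak ×3.0 / ×1.3, and — model-specific — the GPB SR
release Ca²⁺ half-saturation `EC50_SR` ×0.89, the ORd active-CaMKII
fraction ×1.5 (applied to `CaMKa` before the phosphorylated-pathway
fractions are formed), and the ORd non-phosphorylated RyR release
Ca²⁺-sensitivity constant ×0.8 (we scale the 1.5 mM junctional-SR
half-saturation by the tabulated 80%; the direction convention — whether
"80% sensitivity" means a smaller or larger half-saturation — is implicit
in the source and is flagged here deliberately).

The heterogeneous variants start from the homogeneous profile and override
only the Ca²⁺-handling entries with transmurally graded factors: `I_NCX`
2.0× epicardial, 1.6× midmyocardial and endocardial; `J_SERCA` 0.75×
epicardial, 0.60× midmyocardial, 0.45× endocardial.  The factor tables ship
as a structured key-value file (`inst/extdata/hf_remodeling_factors.json`)
— data, not code — and `apply_profile()` maps factor names to model
parameters.  Heterogeneous `I_to` remodeling is deliberately out of scope.

## Fibrosis layouts (the synthetic-input generator)

`insert_diffuse_fibrosis()` reassigns `round(fraction·n)` nodes, drawn
uniformly without replacement by a seeded generator, to the fibroblast
model; `insert_patchy_fibrosis()` converts a contiguous run (25 nodes in
the cluster experiments).  Every element touching a fibroblast node carries
`D/3` (reduced fibroblast–myocyte coupling); we read "fibroblast element"
conservatively as *either endpoint is a fibroblast*.  Identical
`(fraction, seed)` pairs reproduce the layout bit-for-bit, and across seeds
the positions are uniform over the strand (a chi-square check on strand
thirds is part of the test suite).  The study's "11 random configurations"
are reproduced as seeds 1–11 of this generator; the original
configuration 1 is unrecoverable, so configuration-specific values are
treated as stochastic quantities (means over seeds, with at least one seed
expected near the printed configuration).

### How fibroblast nodes couple — an open choice

Two readings of fibroblast–myocyte composition are implemented:

1. **Per-area (default).**  Every node contributes its ionic current per
   unit of its own capacitance and couples through the same operator.  Under
   this reading the diffuse-fibrosis results reproduce quantitatively
   (10% fibrosis lifts APD dispersion several-fold, into the 35-90 ms
   range depending on the configuration, higher still with halved
   coupling), fibroblasts raise the local resting
   potential, and the safety factor inside a 25-node cluster falls to ≈ 1 —
   but propagation does not cross the cluster.
2. **Capacitance-weighted** (`sim_config(fib_cap_coupling = TRUE)`).  The
   diffusion-operator row of a fibroblast node is scaled by the
   myocyte/fibroblast capacitance ratio (≈ 22): per unit of its 6.3-pF
   membrane a fibroblast charges far more easily.  With this weighting and
   the `D/3` reduction confined to myocyte–fibroblast interface elements
   (`fibrosis_d_rule(layout, "interface")`)
   the wavefront crosses the 25-node cluster after a ~40 ms electrotonic
   delay, as in the cluster experiment of the study, at the cost of
   weakening the diffuse-fibrosis effects.

No single setting reproduces both experiment families at once — the
original finite-element implementation is not available to consult — so the
default follows the reading under which the quantitative (diffuse-fibrosis)
targets hold, and the cluster experiment is interpreted through the safety
factor, which behaves identically (≈ 1 inside the cluster) under both
readings.

## Numerics

The solver uses Godunov operator splitting.  Each step advances the
membrane kinetics explicitly at frozen voltage — Rush–Larsen (exact
exponential) updates for Hodgkin–Huxley gates and linear buffers, forward
Euler for the remaining pools — then solves backward-Euler diffusion on the
tridiagonal system from the per-element `D` (Thomas algorithm, prefactored
once), which is unconditionally stable and obeys a discrete maximum
principle.  Three numerical choices deserve note:

* **Stiff compartments.**  The GPB junctional cleft exchanges with the
  subsarcolemmal space at ~46/ms and calsequestrin buffering has a ~10-µs
  time constant; at tissue-solver steps these are advanced by semi-implicit
  exponential updates of the linearized balance `dCa/dt = A − B·Ca`, with
  calsequestrin treated as a rapid-equilibrium buffer.  The
  pure-derivative path keeps the full stiff ODEs, so the reference
  integration is not subject to these approximations.
* **Time step.**  The default `dt = 0.02` ms (the upper limit enforced for
  gating accuracy).  Against a tight-tolerance `lsoda` integration of the
  same kinetics the fixed-step path agrees to 0.04 ms (GPB) / 1.9 ms
  (ORd, 0.3 ms at `dt = 0.005`) in APD90 and to < 1 mV away from the
  upstroke; conduction velocity is anchored by the `κ` calibration at the
  operating step.  The paper-resolution `dt = 0.002` ms remains available.
* **Lookup tables.**  The fixed-step kernels evaluate all
  voltage-dependent kinetic quantities from dense voltage-grid tables
  (0.025 mV spacing; gate slots store `exp(−dt/τ)`) and the
  fractional-power flux terms from log-concentration tables.  Tables hold
  kinetic constants only — every remodelable magnitude enters outside —
  and the derivative path evaluates closed forms, so the two paths check
  each other.

Upstroke times (maximum dV/dt) are tracked at solver resolution inside the
kernel, so conduction measurements do not depend on the trace sampling
interval.  All biomarker threshold crossings interpolate linearly between
samples; ties break to the first crossing.

## Pacing protocols and problem sizes

Strands are paced at the endocardial end (first three myocyte nodes,
40 µA/µF for 2 ms — comfortably suprathreshold; fibroblast nodes are never
stimulated directly) at a basic cycle length of 1000 ms.  The study's full
steady-state protocol (200 s for the two-class strand, 750 s for the
three-class strand) is impractical as a default; the package's scaled-down
default is **30 pre-pacing beats** (GPB strands; 20–50 for ORd runs in the
scripts), after which the per-node APD90 changes by well under 1 ms per
beat (the convergence metric reported by `pace_to_steady_state()`).  A
self-convergence check (30 vs 60 beats, control strand) moves APD
dispersion by ~1.4 ms; values quoted below are at the 30-beat default.
`measure_erp()` bisects the S1–S2 interval to 1-ms resolution from the
steady-state checkpoint, re-using the same checkpoint for every trial;
"propagation" means a fresh upward crossing of −20 mV at the last myocyte
node (the voltage criterion is our documented choice; the source states
none).

## Biomarkers

* **APD90**: maximum-upstroke to 90% repolarization, `V_rest` taken as the
  diastolic (pre-upstroke) minimum of the analyzed window.  A
  foot-referenced `V_rest` (the potential ~1 ms before the upstroke, i.e.
  on the electrotonic foot) was evaluated and rejected: it mixes
  activation information into a repolarization biomarker and is not
  invariant to the trace sampling interval.
* **Dispersion**: interior max − min with 15 cells excluded at each end
  (applied uniformly to APD90, RT, CaTD80 and AP–Ca delay); fibroblast and
  non-captured nodes are excluded.
* **RT / TDR**: RT = activation delay + APD90; TDR = interior RT range.
* **CaTD80 / AP–Ca delay**: Ca²⁺-transient duration from its upstroke to
  80% recovery; delay between voltage and Ca²⁺ upstrokes.
* **CV**: distance over upstroke-time difference between cells 15 and 150.
* **Safety factor**: `SF = (∫I_c + ∫I_out) / ∫I_in` over the
  depolarization window from `t_1%` — read as 1% of the upstroke excursion
  above rest — to the V_m maximum, with `I_c = dV/dt` per unit capacitance
  and the axial terms sign-resolved from neighbor voltage differences.  A
  brute-force re-integration path exists purely to verify the vectorized
  implementation (they agree to < 1%).
* **Welch two-sample t-test** for the seeded-configuration comparisons.

## What the tests do and do not show

The synthetic layouts emulate the study's strand compositions and seeded
fibrosis patterns exactly; they do not emulate spatially correlated
fibrosis textures, 2-D/3-D geometry, or beat-to-beat variability, so green
tests certify the 1-D modeling chain, not clinical generality.  Known
quantitative residuals of our base-model transcriptions, measured against
the study's printed values and left visible as failing checks rather than
absorbed into tolerances: the fibroblast rest (−49.0 vs −49.6 mV), the
control-strand APD dispersion (22.4 vs 20 ± 2 ms), and the ERP pair
(306/388 vs 320/444 ms — the HF gap pointing at the late-Na⁺-current
lineage of the failing GPB variant, whose exact `G_NaL` the study does not
print).  Directional findings — remodeling prolongs APD everywhere, M cells
raise gradients, fibrosis and uncoupling raise dispersion and depress CV
with the 20%-vs-10% biphasic mean, SF ≈ 1 inside clusters — are robust to
these residuals.

## Limitations

One-dimensional, isotropic-per-element monodomain only; no restitution or
alternans protocols; no pseudo-ECG; the fibroblast model is rat-derived (no
human ventricular fibroblast formulation exists); heterogeneous `I_to`
remodeling and β-adrenergic signaling are out of scope; and both myocyte
models inherit their own published idiosyncrasies (the GPB formulation
fixes intracellular K⁺, and the two models disagree on K⁺-current and
Ca²⁺-handling detail, which is precisely why both are carried).
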