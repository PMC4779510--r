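---
title: "Engineering a ventricular biopacemaker in silico: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering a ventricular biopacemaker in silico: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Working ventricular myocardium is electrically quiescent: the inward-rectifier
potassium current IK1 clamps the resting potential near the potassium reversal
potential, and a myocyte fires only when a propagating wave depolarizes it.
Gene- and cell-therapy experiments have shown that suppressing IK1 (e.g. by
dominant-negative Kir2.1 constructs) converts ventricular myocytes into
*automatic cells* (ACs) with spontaneous diastolic depolarization — candidate
biological pacemakers for patients in whom an electronic device is
contraindicated or temporarily removed.

Whether a patch of such cells can actually pace the surrounding heart is a
source–sink problem. Each AC supplies a small depolarizing current; the
surrounding quiescent tissue is a large hyperpolarizing load. A pacemaker patch
coupled directly to the myocardium is typically silenced by its own load,
which is why the native sinoatrial node is partially insulated from the atrium
and why this package's pacemaker geometry couples the AC block to the
ventricular sheet only through a narrow Purkinje-fibre exit path.

`ventpace` simulates this system end to end: single cells, 1D cables, and 2D
monodomain tissue with electrically insulated subregions, plus a pseudo-ECG of
the resulting activity and the analysis utilities needed to quantify pacing.

## Cell models

Ventricular myocytes use the ten Tusscher–Panfilov (2006) human ventricular
model in its three transmural variants (ENDO / MID / EPI: 19 state variables,
12 membrane currents, dyadic-subspace calcium cycling with analytic
steady-state buffering). Purkinje cells use the Stewart et al. (2009) model,
which modifies that framework with a funny current (carried as separate Na⁺
and K⁺ components), a sustained outward current, altered transient-outward
kinetics and a shifted, voltage-gated inward rectifier; it is intrinsically
automatic. All parameters are the published values. One parameter is exposed
for engineering: the maximal IK1 conductance `g_k1` (nS/pF), because setting

```{r}
ac <- cell_params("ENDO", g_k1 = 0.05)   # automatic cell
vm <- cell_params("ENDO")                # quiescent myocyte, g_k1 = 5.405
```

is precisely how an AC is made from an endocardial myocyte. Initial states
are the published resting/initial conditions of each model
(`init_state()`).

A deliberate point about the Purkinje model: its funny current is part of the
published formulation and is kept; the package's "no I_f" restriction applies
to the engineered ACs, which gain automaticity purely by IK1 suppression, with
no added HCN-type current.

## Numerics

* **Gating variables** advance by Rush–Larsen exponential updates
  (`g ← g∞ + (g − g∞)·e^(−dt/τ)`), unconditionally stable and range-preserving:
  gates cannot leave [0, 1] at any step size. The calcium-dependent
  inactivation gate and the ryanodine-receptor availability variable follow
  the same exponential/Euler treatment as the reference implementation of the
  ventricular model.
* **Membrane potential and concentrations** advance by forward Euler; calcium
  compartments use the analytic quadratic buffering update.
* **Default step** `dt = 0.02 ms`. Halving it changes the measured stable
  cycle length by well under 1 ms; the one-step self-consistency of the scheme
  is tested directly (one step at `dt` versus two at `dt/2`).
* **Tissue coupling** is the 2D monodomain model: `∂V/∂t = −I_ion/C_m + DΔV`
  with a scalar diffusion coefficient `D = 0.00154 cm²/ms`, a 4-neighbour
  finite-difference Laplacian at spacing `dh = 0.33 mm`, and first-order
  operator splitting (the step's diffusion increment, computed from
  start-of-step voltages, is folded into each cell's ionic update).
  Zero-flux (Neumann) boundaries are realized by simply omitting uncoupled or
  out-of-domain edges — a mirrored ghost value contributes nothing — so the
  diffusion operator conserves its integral exactly (tested). The stability
  bound `D·dt/dh² < 0.25` is checked before stepping; at the defaults the
  ratio is 0.028.
* **Insulation** is per-edge: the coupling mask deletes every AC/Purkinje-to-
  myocyte edge except through the designated exit window. An insulated block
  is *exactly* flux-free: the myocardial side of such a grid evolves
  bit-identically to a grid in which the block is absent (tested).
* **Performance.** Voltage-dependent rate expressions are tabulated on a
  0.05 mV grid over ±200 mV with linear interpolation, rebuilt whenever `dt`
  changes; a closed-form evaluation path is kept and cross-checked (1,000 ms
  of firing agrees to ~10⁻⁴ mV). Runs are deterministic: identical inputs give
  bit-identical traces, and a run resumed from a returned final state
  continues exactly as an uninterrupted run, which is how long simulations
  checkpoint.

## Geometries

`build_chain(n_ac, n_vm)` — the 1D source–sink experiment: `n_ac` ACs and
`n_vm` myocytes in a cable with the normal tissue `D` and `dh`, all edges
coupled. The driving experiment (`min_acs_to_drive()`) searches ascending
`n_ac` for the smallest chain whose myocyte crosses 0 mV (a full action
potential, not a subthreshold bump) within the horizon.

`build_fig2_layout()` — the insulated pacemaker: a 5 × 30-element AC block
(150 cells), a Purkinje strand 5 elements wide and 50 long (250 elements,
16.5 mm at `dh = 0.33 mm`), the distal 5 × 5 elements forming the 25-element
exit window, attached to a rectangular myocyte sheet. The printed strand
dimensions admit two readings ("50 wide × 5 long" versus 250 elements
spanning 16.5 mm); only a 5-wide × 50-long strand is consistent with all
three numbers at once, so that reading is built.

`build_fig9_layout()` — the idealized sheet: 400 × 100 myocytes, a
1000-cell pacemaker (10 × 100), and a 7.5 mm strand; `round(7.5/0.33) = 23`
elements, i.e. the strand is 7.59 mm as built — the rounding is upward and
documented here. Exit window again the distal 5 × 5.

`build_direct_block(n_ac)` — a near-square AC block fully coupled inside a
myocyte sheet, with no insulation: the stalemate experiment, in which the
block's diastolic depolarization is clamped by the surrounding load.

Grids serialize to a self-describing plain-text container
(`write_tissue_grid()` / `read_tissue_grid()`), with 0-based row/col
conventions recorded in the header.

## Action-potential analysis

Upstrokes are positive-going crossings of −20 mV with a 50 ms refractory
guard and linear interpolation of the crossing instant. The −20 mV default
sits above the diastolic drift of IK1-suppressed cells and below the
overshoot; a separate 0 mV criterion defines "full AP" for driven myocytes.
Cycle lengths are successive upstroke differences; windowed means
(`mean_cycle_length()`) use only upstroke pairs that fall entirely inside the
window, and report `NA` ("undefined") with fewer than two upstrokes. A trace
is *automatic* when a stimulus-free window contains at least two upstrokes.
`find_automaticity_threshold()` bisects `g_k1` between an automatic and a
quiescent endpoint under that classification.

Two operational choices deserve emphasis because results depend on them:

* **Observation window for automaticity.** Near the automaticity boundary the
  first spontaneous beat appears only after a long concentration drift — the
  onset delay grows from < 1 s at `g_k1 = 0.15` to minutes around 0.3–0.5
  nS/pF, and above ≈ 0.5–1 nS/pF the drift re-stabilizes without ever firing.
  The bisection threshold is therefore window-dependent (≈ 0.19 nS/pF at 30 s
  windows, ≈ 0.5 at 600 s in this implementation), and the window is an
  explicit argument rather than a hidden constant.
* **Transient versus stable cycle length.** After IK1 suppression the cycle
  length drifts for hundreds of seconds while Na⁺/K⁺ re-equilibrate; "stable"
  quantities are measured after 500,000 ms, in 10,000 ms windows. Early-window
  values (e.g. over 70–80 s) are properties of the transient and hence of the
  initial state; only post-500 s values should be compared across
  implementations.

## Pseudo-ECG

The far-field proxy is the dipole integral of the membrane-potential
gradient over the tissue, discretized as

ECG = −σ · Σ 1/r³ · [(x−x₀)·∂Vm/∂x + (y−y₀)·∂Vm/∂y] · ΔxΔy,

with central differences in the interior, one-sided differences on borders
and beside VOID pixels, distances in pixel units, and σ = 1 by default (the
trace is in arbitrary units; linearity in σ and in the field is tested).
Electrode coordinates are (x = column, y = row); the electrode may sit outside
the tissue but not on a tissue pixel. Two caveats: the sign convention above
(the one adopted throughout the package) is the negative of the equally common
`+σ` dipole form, so deflection polarity should not be compared across
conventions; and a transmurally homogeneous sheet produces a discordant
repolarization wave — concordant T waves require the transmural heterogeneity
of real ventricular walls, which the idealized geometries here do not include.
Tests therefore pin the quadrature against a brute-force oracle and the
biphasic shape of a passing front, not absolute polarity.

## What the procedural geometries do and do not emulate

The builders reproduce the *published element counts and coupling topology*
(block sizes, strand length, exit-window size, insulation) on idealized
rectangular sheets. They do not emulate: realistic ventricular-slice anatomy
(the original slice geometry is not deposited, so every number tied to it —
e.g. realistic-slice pacing periods or direct-coupling cell counts — is out of
reach by construction); transmural ENDO/M/EPI layering (sheets are uniform
ENDO by default); fibre anisotropy (scalar D); and reduced intercellular
coupling inside the pacemaker. Passing tests therefore validate the method and
its idealized-geometry claims, not patient-specific or slice-specific numbers.

## Problem sizes used by the test-suite

Chosen so the whole suite runs on one CPU in minutes, as the package's own
test policy:

* single-cell stable-state runs: 510,000 ms (the stabilization mark plus one
  10,000 ms averaging window);
* source–sink search: chains up to 8 ACs, 900,000 ms horizon each;
* scaled idealized sheet: 20 × 40 myocytes for 20,000 ms as a smoke/property
  run (the full 400 × 100 sheet over 600,000 ms is an extended target,
  runnable overnight via `run_experiment(default_config("sheet"))`);
* mesh-refinement check: conduction arrival on a 13.2 mm cable at
  `dh = 0.165` versus `0.0825 mm` (3–4 % change). At the production spacing of
  0.33 mm, halving `dh` still changes arrival times by ≈ 11 % — the
  conduction velocity of coarse finite-difference cardiac grids converges
  slowly, a property inherited from the production discretization rather than
  a defect of the solver.

## Known limitations

* The early-transient cycle length and everything downstream of it depend on
  the initial state of the slow ion concentrations; published initial
  conditions are used, but other choices shift early-window statistics by tens
  of milliseconds while leaving stable-state values essentially unchanged.
* The minimal driving chain is sharply sensitive to the sink: with one driven
  myocyte the implementation finds 5 ACs sufficient (first pacing after
  ≈ 8·10⁵ ms); with two driven myocytes no chain up to 8 ACs paces within
  900 s. Claims about "the" minimal count are meaningful only relative to a
  fully specified cable topology, which is why the topology lives in the
  configuration.
* The bisection "automaticity threshold" is meaningful only jointly with its
  observation window (see above).
* No bidomain electrics, no anisotropy, no 3D, no temperature or drug effects.
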