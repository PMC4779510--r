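# ventpace

Simulation of engineered biopacemakers in human ventricular tissue.

Quiescent ventricular myocytes can be turned into spontaneously firing
*automatic cells* (ACs) by suppressing the inward-rectifier potassium current
I<sub>K1</sub> — lowering its maximal conductance G<sub>K1</sub> from the
normal 5.405 nS/pF to ~0.05 nS/pF unmasks diastolic depolarization. A patch of
such cells is a candidate biological pacemaker, but a small depolarizing
source coupled directly to a large quiescent sink is silenced by its own load
(source–sink mismatch). `ventpace` is for computational cardiac
electrophysiologists who want to study this trade-off quantitatively: how many
ACs does it take to drive quiescent tissue, and how should a pacemaker be
insulated and routed through a Purkinje-fibre exit so that a small patch paces
a whole sheet?

## What is inside

* **Ionic cell models** — the ten Tusscher–Panfilov (2006) human ventricular
  myocyte (ENDO / MID / EPI variants) and the Stewart et al. (2009) Purkinje
  fibre cell, implemented from their published parameter sets, with
  G<sub>K1</sub> exposed as the engineering parameter. Single cells follow
  dV/dt = −I<sub>ion</sub>/C<sub>m</sub>, I<sub>ion</sub> = I<sub>Na</sub> +
  I<sub>K1</sub> + I<sub>to</sub> + I<sub>Kr</sub> + I<sub>Ks</sub> +
  I<sub>CaL</sub> + I<sub>NaCa</sub> + I<sub>NaK</sub> + I<sub>pK</sub> +
  I<sub>pCa</sub> + I<sub>bCa</sub> + I<sub>bNa</sub>.
* **2D monodomain solver** — ∂V/∂t = −I<sub>ion</sub>/C<sub>m</sub> + DΔV on a
  labelled pixel grid (D = 0.00154 cm²/ms, dh = 0.33 mm, dt = 0.02 ms), with
  per-edge coupling masks that realize electrical insulation and zero-flux
  boundaries; Rush–Larsen gating updates and a compiled (Rcpp) inner loop.
* **Geometry builders** — 1D AC→myocyte chains, an insulated 150-cell
  pacemaker with a 250-element (16.5 mm) Purkinje strand and a 25-element exit
  window, an idealized 400 × 100 sheet with a 1000-cell pacemaker, and a
  directly coupled AC block for the stalemate experiment.
* **Pseudo-ECG** — the dipole integral
  ECG = −σ Σ [(x−x₀)∂V/∂x + (y−y₀)∂V/∂y] / r³ ΔxΔy over the voltage field.
* **Analysis** — upstroke detection, windowed cycle lengths, automaticity
  classification and G<sub>K1</sub>-threshold bisection, first-pacing times,
  and config-driven experiment runners with checkpoint/resume.

## Worked example

```r
library(ventpace)

## one endocardial myocyte turned automatic
ac <- cell_params("ENDO", g_k1 = 0.05)
tr <- run_single_cell(ac, 30000)          # 30 s, no stimulus
detect_upstrokes(tr)
#> <ap_markers> 40 upstrokes, mean CL 758.77 ms
round(mean_cycle_length(detect_upstrokes(tr), 10000, 30000), 1)
#> [1] 755.6

## a scaled idealized sheet: insulated pacemaker + Purkinje exit + myocardium
g <- build_fig9_layout(vm_rows = 20, vm_cols = 40)
g
#> <tissue_grid> 20 x 73 pixels, dh = 0.33 mm, D = 0.00154 cm^2/ms
#>          VOID       VM_ENDO            AC      PURKINJE PURKINJE_EXIT
#>           345           800           200            90            25

run <- run_tissue(g, 5000)                # 5 s of tissue activity
vm_mid <- data.frame(time = run$traces$time, vm = run$traces$vm_mid)
detect_upstrokes(vm_mid)
#> <ap_markers> 6 upstrokes, mean CL 865.985 ms
round(first_pacing_time(vm_mid), 1)
#> [1] 251.8
```

The automatic cell fires with a spontaneous cycle length around 756 ms this
early in its slow transient (it settles near 858 ms after 500 s). The
insulated pacemaker captures the myocardial sheet 252 ms into the simulation
and then paces it at the pacemaker's own rhythm — the probe in the middle of
the sheet fires once per pacemaker cycle.

Command-line front end for the full experiments (configs in YAML, artifacts
as CSV + YAML summaries):

```sh
Rscript inst/cli/ventpace.R single-cell --out out/
Rscript inst/cli/ventpace.R sheet --set layout=fig9 --set snapshot_dt=1 --out out/
```

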