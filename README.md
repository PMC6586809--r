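# coroflow

Simulated coronary hemodynamics from biplane-projection geometry, built to
study one question: **how much do side branches matter?** A 3D model of a
coronary artery tree that omits side branches forces their flow through the
main vessels and distorts the endothelial shear stress (ESS) — the
frictional traction of blood on the wall whose low values (≲ 1–2 Pa) mark
atherosclerosis-prone segments. `coroflow` implements the full protocol on
synthetic anatomy:

* **Synthetic trees** — left (LM → LAD/LCx with diagonals and marginals) or
  right coronary templates: tapered centerline polylines, take-off cones,
  cosine-bell stenoses, every side branch > 1 mm ostial diameter,
  seed-deterministic.
* **Biplane projection & reconstruction** — cone-beam C-arm projection at
  clinical RAO/LAO + cranial/caudal angles (separation > 45° enforced);
  reconstruction by monotone dynamic programming on epipolar residuals,
  common-perpendicular triangulation and magnification-corrected diameter
  recovery. The noise-free round trip is exact to ~1e-13 mm.
* **Meshing & voxels** — watertight lumen surfaces by marching tetrahedra
  on implicit tube-union distance fields; STL I/O; voxelization with
  inlet/outlet disk labelling; branch pruning (complete → matched model);
  symmetric Hausdorff distance; N-point rigid registration.
* **Flow** — a D3Q19 lattice-Boltzmann solver (regularized BGK / TRT) with
  a Poiseuille piston inlet driven by a packaged diastolic-dominant
  waveform, lumped microcirculation-resistance outlets distributed by
  Murray's law (`R_i ∝ d_i^-3`), interpolated bounce-back walls, and wall
  shear extracted from non-equilibrium moments. Blood: μ = 4 cP,
  ρ = 1060 kg/m³, rigid walls.
* **Analysis** — time-averaged ESS (TAESS) on 0.3 mm centerline sections,
  circumferential averaging, 2D cylindrical wall maps, point-to-point
  complete-vs-matched comparison with a 0.5 Pa threshold, four shear bands
  (< 1 / 1–2 / 2–3 / ≥ 3 Pa), per-vessel volumetric outflow, and the
  standard statistical suite (KS, t, Kruskal–Wallis, Friedman).

The core quantities, in the field's notation: wall shear for developed tube
flow `τ_w = 4 μ v̄ / R`, pressure drop `ΔP = 8 μ L Q / (π R⁴)`, TAESS
`= (1/T) ∫ |τ_w(t)| dt`, and the lumped outlet relation `P_k = Q_k R_k`
with `1/R_tot = Σ 1/R_i`, `R_i ∝ d_i^{-3}`.

## A worked example

The packaged branch-removal experiment: simulate a full left tree, measure
the flow entering the LAD, then re-simulate the LAD as a standalone model
with 3, 2, 1 and 0 diagonal branches at that matched inflow (two pulsatile
cardiac cycles each):

```r
library(coroflow)
abl <- run_lad_ablation(ablation_config(seed = 3))
abl
#> # A tibble: 4 x 5
#>       k trunk_taess trunk_sections lad_outflow_mls periodicity
#>   <int>       <dbl>          <int>           <dbl>       <dbl>
#> 1     3        1.49            119           0.154      0.142
#> 2     2        1.91            119           0.223      0.102
#> 3     1        2.38            119           0.340      0.0805
#> 4     0        3.26            119           0.694      0.0469
```

Reading the table: `trunk_taess` is the TAESS (Pa) averaged over the 119
0.3 mm sections of the LAD trunk, and `lad_outflow_mls` the terminal LAD
outflow (ml/s). As diagonals are removed the matched inflow is forced
through the trunk: trunk shear rises monotonically and more than doubles
from the full model (1.49 Pa) to the branchless one (3.26 Pa), while the
terminal outflow grows 4.5-fold — branch omission biases both ESS and
flow distribution, which is the package's central reproducible finding.
`autoplot(abl)` draws the dose–response; `run_full_study(run_config(seed =
1))` runs the complete CCM-vs-MCM pipeline end to end and
`run_hd_matrix(n = 5)` the Hausdorff-based anatomy-matching matrix.

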