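---
title: "Methods: side-branch effects on simulated coronary hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: side-branch effects on simulated coronary hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(coroflow)
```

## The question the package addresses

Computational models of coronary blood flow are usually built from a 3D
reconstruction of the arterial tree, and the endothelial shear stress (ESS)
they predict — the tangential frictional traction of blood on the vessel
wall, whose low values (below roughly 1–2 Pa) are considered
pro-atherogenic — depends on how much of the tree the reconstruction
captures. Side branches steal flow from the main vessels; a model that
omits branches below some visibility threshold forces that flow through the
trunk and overestimates trunk shear. `coroflow` implements, on fully
synthetic anatomy, the complete protocol needed to study this effect:
generation of coronary-like trees, biplane angiographic projection and 3D
reconstruction, surface lofting and voxelization, lattice-Boltzmann flow
simulation with physiological boundary conditions, and the reduction of the
resulting wall-shear fields to the standard comparison quantities
(time-averaged ESS on 0.3 mm centerline sections, complete-versus-matched
model differences, shear-band strata, per-vessel outflow).

Everything here runs at *desk scale* — single CPU, minutes — and the
package is explicit about what that buys and what it does not: the
qualitative physics of branch steal, flow splits and shear stratification
are faithfully reproduced and validated against analytic oracles, while the
absolute patient-cohort numbers of clinical studies (which require
patient-specific anatomy at resolutions near 50 µm) are out of reach by
design.

## Synthetic anatomy

`generate_tree()` builds a rooted tree of vessel segments: ordered 3D
centerline polylines with per-point lumen radii (all lengths in mm). The
left template grows a left main that bifurcates into LAD and LCx with
diagonal and obtuse-marginal side branches; the right template a single RCA
trunk with acute-marginal branches. Radii taper linearly with arclength;
side branches take off at angles drawn uniformly inside a configurable cone
(default 35–65°) and every generated branch has an ostial diameter above
1 mm — the inclusion rule for angiographically identifiable branches —
unless deliberately overridden. Branch placement is rejection-sampled: a
candidate polyline must clear every existing segment (outside its own
junction-blending neighbourhood) by 0.1 mm, with up to 60 redraws that
progressively nudge the attachment distally and widen the main bifurcation.
This makes all 100 generation seeds used in the test-suite produce valid,
non-self-intersecting trees for both the physiological default morphometry
and the compact desk-scale variants.

Because no morphometric distributions of a patient cohort are available to
fit, the defaults are physiologic textbook values (left main ~4.5 mm
diameter, LAD ~110 mm long tapering 3.7 to 1.2 mm, and so on); the compact
trees used in the simulation studies are stated where they are used and are
deliberately small so that the flow solver resolves them on one CPU.

Focal stenoses are modelled as a cosine-bell diameter reduction: the radius
profile is multiplied by $1 - \tfrac{s}{2}(1+\cos(2\pi (x-c)/L))$ inside
the lesion of length $L$ centred at $c$, reaching fractional diameter
reduction $s$ at the centre and returning smoothly ($C^1$) to the reference
taper at the edges. The centerline is refined so the lesion landmarks fall
exactly on sample points, which lets tests assert the profile in closed
form.

## Projection and reconstruction

The projection model is a cone-beam (perspective) camera per view: a point
X-ray source at the configured source–isocenter distance, a detector plane
at the source–detector distance, clinical RAO/LAO and cranial/caudal angles
composed primary-then-secondary, pixel (0,0) top-left. Projected vessel
width is twice the radius times the local magnification (source–detector
over point depth). Construction of a gantry pair fails unless the two view
axes are more than 45° apart — the well-posedness condition for two-view
reconstruction.

Reconstruction inverts this in three steps. `correspond_points()` matches
the two projected centerlines of each segment by dynamic programming over
monotone alignments with the epipolar residual (pixel distance of a point
in view B from the epipolar line of its partner in A) as cost; centerlines
are ordered curves, so the monotone alignment is globally optimal and
deterministic. `triangulate_matches()` back-projects each matched pair to
two rays and takes the midpoint of their common perpendicular; the miss
distance is kept as a per-point quality metric, and nearly parallel
(foreshortened) rays are interpolated from neighbours instead of
triangulated. `recover_diameters()` converts projected widths back to radii
using the magnification recomputed at the reconstructed depth, averaging
the two views and reporting their disagreement. Segment labels (and
parenthood) ride through projection, so reconstruction accuracy is
measurable per segment; unlabeled cross-branch matching is intentionally
out of scope, mirroring operator-identified vessels in clinical practice.

The noise-free round trip (generate, project, reconstruct) recovers
centerlines to ~1e-13 mm and is the module's primary invariant; with
Gaussian pixel jitter the error grows continuously, which the test-suite
verifies in expectation over 20 seeds per noise level.

## Surfaces, voxels and geometry metrics

Lumen surfaces are the implicit union of tapered-capsule distance fields
(one per centerline piece), cut flat at the inlet and at every outlet by
localized half-space caps, and extracted by marching tetrahedra: each cube
of the sampling grid is split into six tetrahedra sharing its main
diagonal, so adjacent cubes agree on shared faces and the triangulation is
closed and consistently oriented by construction. Watertightness is checked
(every undirected edge in exactly two triangles, every directed edge once)
rather than assumed. A lateral surface of a lofted 20 mm, 1.5 mm-radius
tube agrees with $2\pi R L$ to ~0.1%.

Voxelization classifies voxel centers against the same implicit field (the
mesh carries it), keeps the single 26-connected fluid component containing
the inlet, identifies inlet/outlet disks from the cap records, and
annotates wall-adjacent voxels with wall distance, outward normal, owning
segment, arclength and local radius. The grid origin is offset by $h/\pi$
so that voxel centers never lie exactly on analytically placed surfaces —
without this, lattice-commensurate geometries (a radius equal to an integer
number of spacings) degenerate half the boundary links and visibly inflate
the discrete wall drag.

The Hausdorff distance between meshes is computed from seeded area-weighted
surface samples with exact point-to-triangle distances (uniform-grid
accelerated); two unit spheres three millimetres apart measure 3.000 ± 0.01.
Rigid landmark registration is the Kabsch algorithm with a reflection
guard, and `landmark_cartesian_distance()` provides the per-location
Euclidean comparison used for phantom-style validation.

## The flow solver

The solver is a D3Q19 lattice-Boltzmann method written for this package
(single fused pull pass per step in C++). Blood is Newtonian and
incompressible with dynamic viscosity 4 cP and density 1060 kg/m³; walls
are rigid with no slip. These assumptions are standard for coronary-scale
CFD and are retained deliberately.

**Collision.** Three operators are available: plain BGK, a
Hermite-regularized BGK (the default), and a two-relaxation-time (TRT)
operator with configurable magic parameter Λ (default 0.03). At the
physical viscosity and desk-scale resolutions the relaxation time τ sits
barely above its lower limit of 1/2 (τ ≈ 0.5015–0.51), where plain BGK is
unstable; the regularization projects the non-equilibrium part onto its
second-order moment and is the minimal stabilization that keeps the
single-relaxation-time character. TRT improves wall placement and costs
less per step, but its wall-exact Λ = 3/16 is advectively unstable in this
τ range; Λ = 0.03 is the compromise used where TRT is selected.

**Unit mapping.** The spatial step is the voxel spacing; the time step is
set so the estimated peak velocity maps to a target lattice Mach number
(default 0.05, capped below 0.1), and τ follows from
$\nu = c_s^2(\tau - \tfrac12)\,\Delta t$. The peak-velocity estimate uses
the package's own lumped (0D) network solution: per segment, twice the mean
velocity at the narrowest cross-section carrying that segment's flow, times
the waveform peak and a 25% headroom. A conservative estimate costs steps;
an optimistic one violates the Mach target — the 0D estimate threads this
needle without hand tuning per geometry.

**Boundaries.** All boundary conditions are link-wise:

* *Walls*: interpolated (Bouzidi linear) bounce-back with the exact
  link-wall intersection fraction from the implicit lumen field, falling
  back to halfway bounce-back when τ < 0.503, where the interpolation
  feeds an unstable near-wall mode. Interpolated bounce-back does not
  conserve mass on oblique walls (we measured ~4% leakage on a 35°
  bifurcation), so the per-node interpolation mass defect is restored
  isotropically — this makes the wall exchange mass exactly like
  bounce-back while keeping the improved wall placement.
* *Inlet*: a permeable moving-wall bounce-back piston imposing the
  parabolic (Poiseuille) profile scaled by the inflow waveform, with the
  link coefficients normalized so the injected flux equals
  $\bar v \pi R^2$ exactly (rim links are partially wall-blocked and would
  otherwise under-inject by several percent).
* *Outlets*: anti-bounce-back against the lumped microcirculation pressure
  $P_k = Q_k R_k$. Outlet flows are measured as the exact link-wise
  boundary mass flux (a one-voxel oblique measurement layer overcounts
  area by the Manhattan factor; link flux has no such bias), low-pass
  filtered, and the common pressure offset is anchored to the plain mean
  (a common offset does not affect incompressible flow, and unlike a
  flow-weighted mean the plain mean stays finite through systolic flow
  reversals). Each outlet's filter gain is scaled by the ratio of its
  internal Poiseuille path resistance to its lumped resistance, computed
  from the 0D network: the explicit 3D–0D coupling is a fixed-point
  iteration whose differential gain is that ratio, and short wide branches
  oscillate without this scaling. Gauge densities are clamped to ±9%.

**Outlet resistances.** `assign_resistances()` sets the total
microcirculation resistance from mean aortic pressure over total mean flow
and distributes it in parallel with conductances proportional to the cubed
outlet diameter (Murray's law; the exponent is configurable), so the
parallel combination equals the total exactly.

**Wall shear.** The deviatoric stress is reconstructed from non-equilibrium
moments at wall-adjacent voxels, contracted with the implicit-surface
normal, projected tangentially, and linearly extrapolated from the voxel
center to the wall using the known wall distance and local lumen radius
(shear varies approximately linearly across a vessel cross-section). TAESS
is the trapezoidal time average of the tangential magnitude over one
cardiac cycle, treating the recording as periodic.

**Inflow waveform.** A two-phase, diastolic-dominant periodic waveform
(systolic dip to ~0.4 of mean, diastolic peak ~1.55) with unit mean is
shipped as a plain CSV and is fully user-replaceable; the cardiac period
defaults to 0.8 s, the mean inlet velocity to 0.25 m/s steady (average
diastole) and 0.28 m/s pulsatile.

**Convergence.** Steady runs monitor the domain-mean speed and additionally
require the inflow/outflow imbalance below 0.5% — the velocity residual
alone converges long before the slow mass/pressure transient of the
lumped-outlet loop. Transient runs check cycle-to-cycle periodicity of the
outlet flows and warn with the achieved residual when the requested number
of cycles is not enough (with two cycles and the under-relaxed outlet
filter, 5–15% residuals are typical and documented in the outputs).

### Validation and its limits

The solver is validated against analytic oracles in the test-suite, at the
problem sizes the package is designed for:

* steady Poiseuille flow in a 1.5 mm-radius tube at 0.28 m/s and 20 voxels
  per diameter: centerline velocity within 2%, wall shear within 5% of
  $4\mu\bar v/R$, and the developed pressure gradient within 5% of
  $8\mu L Q/(\pi R^4)$. The gradient is measured in the distal window of a
  42 mm tube: at Re ≈ 223 the entrance length exceeds short tubes, and the
  developing-flow excess would otherwise contaminate the slope;
* flow splits of symmetric and Murray-weighted bifurcations against the
  independent 0D resistor network (tube Poiseuille resistances in series
  with the outlet resistances): within 1% and 5% respectively, with exact
  global mass balance;
* quasi-steady tracking of the waveform in a pulsatile tube at low
  Womersley number within 10%.

The main accuracy limiters, in order: the staircase description of curved
walls at 5–20 voxels per diameter; the τ → 1/2 regime forced by physical
blood viscosity at desk resolutions (grid Reynolds numbers of order 100 are
the practical stability ceiling — geometries are sized so local peak
velocities stay below that limit); and weak compressibility at lattice Mach
numbers up to 0.1 (order 1% density variation).

## The analysis chain

`section_centerline()` resamples every segment at 0.3 mm; a segment of
length $L$ yields exactly $\lfloor L/0.3\rfloor + 1$ sections, and a
~600 mm tree about 2000, matching the resolution at which clinical
ESS-mapping studies report. `circumferential_average()` assigns each wall
sample to its nearest section by arclength and averages; empty sections are
flagged, never dropped silently. `cylindrical_map()` unrolls one vessel
into an arclength-by-angle image with a parallel-transported angular
reference. `compare_point_to_point()` matches sections between a complete
model (CCM) and a pruned, matched model (MCM) by segment label and section
index — pruning leaves the retained geometry bitwise unchanged, so this
matching is exact by construction rather than by nearest-neighbour search —
excludes CCM-only branches with reasons, and reports the fraction of pairs
differing by more than the 0.5 Pa threshold. `stratify()` classifies
sections into the four bands (low < 1 Pa, intermediate 1 to < 2, high 2 to
< 3, very high ≥ 3); values exactly on a boundary go to the higher band, a
deliberate resolution of the ambiguity in the conventional interval
notation, and the boundaries are configurable. Both reductions are tested
to agree *exactly* with brute-force enumeration on randomized profiles.
`outflow_report()` averages outlet flow over the final cycle and groups
outlets into major vessels by ancestry; `stats_suite()` runs the
conventional reporting chain (Kolmogorov–Smirnov normality per group, mean
± SEM, two-tailed t test for two groups, Kruskal–Wallis or Friedman beyond
that, significance at p < 0.05).

## The packaged experiments

`run_full_study()` chains the whole pipeline — synthesize, project,
reconstruct, loft, voxelize, prune to the matched model, simulate both with
identical inflow, analyze — persisting every artifact and writing a
canonical JSON report whose checksum is reproducible bit-for-bit for a
fixed seed. The default configuration is sized to finish a run in about a
minute (compact left tree, 0.3 mm voxels, steady inflow).

`run_lad_ablation()` reproduces the branch-removal experiment: the full
left tree is simulated once at the steady cycle-mean inflow to measure the
flow entering the LAD; the LAD subtree is then extracted and simulated
standalone with 3, 2, 1 and 0 diagonals under two pulsatile cycles, every
submodel's inflow matched to that measured LAD inflow. Two design choices
matter here and were made for stated physical reasons:

* *Outlet resistances are inherited from the complete submodel*, not
  re-derived per pruned variant: pruning removes branches, not the
  microcirculation downstream of the branches that remain. With fixed
  per-outlet resistances the trunk flow is pointwise non-decreasing under
  branch removal (removing an outlet can only increase every remaining
  section's flow share), which is the clean controlled-experiment version
  of the comparison; re-deriving the distribution per variant redistributes
  flow among the survivors and can genuinely lower mid-trunk flow.
* *Branches are removed proximal-first* (the LAD-2 model keeps the two
  distal diagonals), so the junction-local shear enhancement lost with a
  removed branch is compensated by the flow gain over the longest possible
  trunk run.

The ablation tree (`ablation_config()`) is the study-conditions object: a
compact left tree whose three diagonals carry about three quarters of the
LAD inflow — the regime in which complete clinical reconstructions operate
— with a mild (15% diameter) mid-distal LAD stenosis, 0.28 mm voxels,
Mach 0.095 and two 0.8 s cycles. With it, trunk-averaged TAESS rises
monotonically as diagonals are removed and the no-branch model at least
doubles the full model (about 3.3 vs 1.5 Pa on the packaged seed), while
the terminal LAD outflow grows about four-and-a-half-fold — the same
direction, at desk scale, as the order-of-magnitude contrasts reported for
patient anatomy. The absolute patient percentages are not reproduction
targets: the inputs that produced them do not exist here.

`run_hd_matrix()` runs the matched-versus-unmatched discrimination design:
each synthetic tree gets a smoothly perturbed copy (the stand-in for a
second-modality reconstruction of the same anatomy), and the full
symmetric-Hausdorff cross matrix shows its row minima on the diagonal.

## Numerical choices and degenerate inputs

Tolerances and tie-breaks that affect results are: the 0.1 mm clearance
margin and redraw schedule in tree generation; the $h/\pi$ voxel-grid
offset; Bouzidi link fractions clamped to [0.05, 0.95] and the τ ≥ 0.503
gate; the ±9% outlet gauge clamp; the under-relaxation floor (5e-4) and
ceiling (0.05) of the outlet filter; band boundaries to the higher band;
empty sections flagged and excluded from paired comparisons with reasons;
zero-severity stenoses recorded but geometrically inert; pruning of absent
segments a warning-level no-op (which makes pruning idempotent); and
re-running any stage from persisted artifacts reproduces downstream results
because every stochastic stage derives its seed from the single
configuration seed.

## What passing tests do and do not show

The synthetic generator emulates branching topology, tapering, take-off
geometry and focal stenoses; it does not emulate imaging physics (no
attenuation or motion blur — projections are exact polylines plus optional
Gaussian jitter), cardiac-phase motion, vessel-wall compliance,
non-Newtonian rheology, or the morphometric variability of a patient
cohort. Green tests therefore demonstrate: the geometric pipeline is exact
to numerical precision on its own forward model; the solver reproduces
analytic laminar physics at stated resolutions; the analysis reductions
are exactly the advertised formulas; and the side-branch effect has the
reported direction and at least the asserted magnitude on anatomy in the
clinically relevant flow-sharing regime. They do not certify patient-level
accuracy, absolute cohort percentages, or behaviour at resolutions and
Reynolds numbers beyond the stated stability envelope.
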