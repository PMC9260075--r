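---
title: "A geometric volume-conductor model of cochlear-implant electrode impedance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A geometric volume-conductor model of cochlear-implant electrode impedance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleaVC)
```

## The problem

During cochlear-implant surgery the electrode array is advanced into the
scala tympani essentially blind: the surgeon has no real-time feedback on how
deep the array sits or how close it is to the cochlea wall and the delicate
basilar membrane. Because perilymph (≈1.43 S/m) conducts far better than the
surrounding wall and bone, the impedance between a contact and a distant
return electrode carries positional information: it rises as the array is
inserted deeper and as a contact approaches a poorly conducting boundary.
`cochleaVC` provides a fully parametric, desk-scale simulator of this
measurement: a geometric cochlea volume conductor, a 16-contact
silicone-carrier array, a quasi-static finite-element solver, and the sweep
protocols that map electrode-to-ground impedance against insertion depth,
in-plane proximity, and tissue conductivity.

## Model and assumptions

All tissues are purely resistive and isotropic, so at each instant the
potential obeys the quasi-static Laplace equation

$$\nabla\cdot(\sigma\,\nabla V) = 0,$$

with the outer model surface grounded, $V(\delta\Omega)=0$. Each platinum
contact is an ideal equipotential surface with zero interface impedance; an
active contact carries a prescribed net current $I_{el}$ (34 µA by default)
and its impedance to ground is

$$Z_{el} = V_{el} / I_{el},$$

where $V_{el}$ is the contact's equipotential value. No dielectric or
frequency dependence is modelled, and no electrode–electrolyte double layer:
these match the quasi-static, purely conductive assumption set under which
such impedance maps are normally computed.

### Geometry

The scala tympani is an elliptical tube swept along a conical helix.  Over
the curve parameter the spiral radius interpolates linearly from
`base_radius_m` (2.6 mm) to `apex_radius_m` (1.0 mm) across `n_turns` (2.5)
while rising `axial_pitch_m` (2.1 mm) per turn; the lumen semi-axes taper
linearly in arc length from 1.0 × 0.8 mm to 0.5 × 0.4 mm.  Each cross-section
carries a local frame with `x̂` pointing at the inner (modiolar) wall and
`ŷ` at the basilar-membrane side; array placements are expressed as offsets
in this frame, matching the x/y sweep semantics of intra-cochlear proximity
studies.

Around the lumen sit, as angular sectors of a wrapped layer: the basilar
membrane (top sector, 45°–135°, 50 µm, 0.0125 S/m), the spiral ligament
(lateral sector, 150°–210°, 150 µm, 1.67 S/m) and the cochlea wall
(elsewhere, 100 µm, 0.3 S/m), with smooth 5° thickness blends at the sector
joints.  Outside that layer lies a bone sheath of thickness `bone_margin_m`
(0.3 mm, 0.0156 S/m).  The stria vascularis (0.0053 S/m) is far too thin to
mesh; it enters as a thin-layer *contact impedance* on the interface between
ligament and bone: flux is continuous and the potential jumps by
$(t/\sigma_s)\,j_n$, realised with duplicated interface nodes and a surface
mass-matrix coupling.  The membrane's outer surface is insulated — no
current leaves into the (air-filled) middle-ear side.

No published drawing fixes these dimensions numerically, so the defaults are
literature-typical human values and every length is configurable.  Absolute
impedances are therefore configuration-dependent by design; the package's
claims concern counts, trends, ratios and sensitivities, not kΩ values.

Two deliberate simplifications replace an anatomical temporal-bone block:

* **Bone sheath instead of bone block.** Each turn carries its own bone
  sheath whose outer surface is the ground label `GROUND_OUTER`.  The
  default spiral pitch keeps adjacent turns' sheaths from intersecting
  (checked numerically at mesh time), preserving the non-overlap invariant
  of the solid regions.
* **Basal ground patch.** A real implant returns current to an extracochlear
  electrode near the cochlea's basal entry.  Grounding the *entire* sheath
  would place the sink ~0.3 mm from every contact and wash out the
  insertion-depth dependence the protocols measure; the cochlea protocols
  therefore ground only the basal 2 mm of the sheath
  (`solver_options(ground_mode = "patch")`).  The fully grounded boundary
  remains available (`"outer"`) and is the default for the free-standing
  verification fixtures.

The electrode array is a silicone carrier (σ = 10⁻⁷ S/m) of circular
cross-section (0.3 mm radius) with 16 rectangular contact patches
(0.3 × 0.4 mm at 0.85 mm pitch), numbered E1 at the apical tip to E16 at the
base, facing the modiolar wall.  Contacts are thin plates and are modelled
as boundary surface patches, not solids.  Insertion step *k* places the
carrier so that exactly contacts E1..Ek lie inside the lumen (Ek half a
pitch inside the basal opening); the extracochlear remainder of the array is
not part of the conductive domain — its return-electrode role is played by
the ground patch.

### What the generator does and does not emulate

The generator reproduces the features that drive positional impedance
changes: a tapering, coiling lumen; resistive wall/membrane/ligament/bone
boundaries; a poorly conducting carrier occupying much of the duct; wall
proximity and insertion depth as explicit parameters.  It does **not**
emulate anatomical cross-section irregularity, the scala vestibuli and
modiolus as separate conductors (a scala vestibuli region would sit beyond
the insulated membrane and carry no current, so none is generated),
electrode-array curvature mechanics, or patient variability.
Passing tests therefore demonstrate correctness of the solver and protocol
machinery and the robustness of qualitative trends — not agreement with any
individual cochlea.

## Discretisation

The mesher is structured and boundary-fitted: one triangulated cross-section
template (carrier fan, graded fluid rings, tissue-layer rings, bone rings)
is swept along the centreline; each prism is split into three tetrahedra
with a lowest-vertex-index diagonal rule, which guarantees a conforming mesh
(Dompierre's criterion).  Choices that matter:

* **Area-corrected rings.** Polygonal rings inscribe an ellipse and lose
  $O(m^{-2})$ area; every ring is scaled so its polygon area equals the true
  ellipse area.  With vertices linear in arc length this makes swept region
  volumes match $\int \pi a(s) b(s)\, ds$ to machine precision for linear
  tapers — the mesh-volume tests exploit this.
* **Edge clustering.** Equipotential patch edges carry an $r^{-1/2}$ flux
  singularity.  Angular stations are clustered at the contact band edges and
  the fluid rings grade geometrically (exponent 1.7) towards the carrier
  surface; the disk-contact verification fixture clusters quadratically at
  the disk rim for the same reason.
* **Sizes.** `target_size_near_m` (default 0.15 mm) sets carrier-surface
  angular resolution, axial station spacing along the inserted extent and
  fluid layering; `target_size_far_m` (0.6 mm) sets bone layering and apical
  spacing, approached at `growth_rate` 1.4 per station.  Defaults give
  ~10⁵ tetrahedra and solve in ~1 s; production meshes of millions of
  elements are a configuration choice, not a code path.
* **Elements.** Linear (P1) tetrahedra only.  Accuracy is quantified by
  h-refinement (`run_convergence_study()`; observed order ≈ 1.9 on smooth
  problems) rather than by a second element order.
* **Determinism.** The mesher has no random stage; `mesher_seed` is recorded
  in the provenance but identical inputs always give byte-identical meshes.

## Solver

Contact tying reduces each patch to one master dof, keeping the system
symmetric positive definite; grounding eliminates the Dirichlet nodes.  A
current injection is then a unit load on a terminal dof, so one sparse
Cholesky factorisation serves all contacts of a geometry, and the
transfer-impedance matrix $Z_{ij}$ (voltage at contact *i* per unit current
at *j*) is reciprocal to solver accuracy.  A Jacobi-preconditioned conjugate
gradient solver (relative residual 10⁻¹⁰) is available as an alternative
(`method = "cg"`).  Inactive inserted contacts float as tied equipotential
surfaces by default; the grounded-inactive convention of sequential
measurement protocols is derived exactly from the floating matrix as
$Z^{grounded}_{jj} = 1/(Z^{-1})_{jj}$, and both are reported.  A
uniform-current-density contact mode exists as a cross-check and agrees with
the equipotential mode within ~3% at default resolution.

## Protocols

* `run_sequential_insertion()` rebuilds the geometry for every insertion
  step k = 1..16 and records every inserted contact: 136 records per
  inactive-contact mode.
* `run_insertion_depth_profile()` gives the 16 per-contact impedances at
  full insertion from a single factorisation.
* `make_proximity_grid()` builds the 12 × 12 in-plane placement grid (144
  candidates) with one common spacing *d* sized from the touching offset
  along x, so the outermost candidates are invalid — placements whose
  carrier touches or crosses the scala boundary are flagged
  (`placement_invalid`) and never solved.  `make_proximity_ray()` samples a
  single ray from mid-scala to 95% of the touching offset for the axis
  sweeps.
* `run_conductivity_sensitivity()` rescales one tissue conductivity by
  0.90–1.10 in 5% steps and reports the maximum change of the impedance
  profile after normalising each profile by its own mid-scala value
  ("impedance variation"), alongside the raw absolute shift.  The
  normalised reading operationalises the distinction between the pattern of
  positional impedance variation (what insertion guidance uses) and the
  trivial $1/\sigma$ scaling of absolute impedance.

Problem sizes used by the tests and the acceptance script: meshes of
4–10 × 10⁴ tetrahedra (near size 0.2–0.3 mm), 8-position rays, the full
12 × 12 grid for counting and validity, and 16-step sequential runs — all
sized to finish in minutes on one CPU while leaving trend amplitudes well
above discretisation noise.

## Verification

With no anatomical reference model available, correctness rests on analytic
oracles and invariances, all enforced in the test suite:

* homogeneous and layered bars (exact for P1, since the solution is linear);
* a thin resistive layer in series, $t/(\sigma_s A)$;
* concentric spheres, $R = (1/4\pi\sigma)(1/a - 1/b)$, within 2%;
* a disk contact on a half-space, $R = 1/(4\sigma a)$, within 5%;
* reciprocity and passivity of $Z_{ij}$ (cross-checked against a dense
  resistor-network computation), conductivity scaling $Z \propto 1/\sigma$,
  geometric scaling $Z \propto 1/L$, current-magnitude invariance, current
  conservation, and the discrete maximum principle.

## Known limitations

* **Absolute impedance values** depend on the configured dimensions; only
  orders of magnitude (2–7 kΩ at defaults) are meaningful.
* **Near-wall surge magnitude.** Measured and anatomical-model studies
  report sharp (up to 14-fold) impedance rises very close to the cochlea
  wall.  In this model a rigid in-plane translation leaves the perilymph
  return-path cross-section area unchanged, so with a basal current sink
  only the contact's local access resistance grows near the wall: Z rises
  monotonically but by ~10–40%, not multiples.  Reproducing the surge
  appears to require a three-dimensionally grounded anatomical embedding
  (and its exact lumen/carrier clearances), which is outside this
  geometric model's scope.
* **Remeshing noise.** Impedances carry ~1% discretisation noise at default
  resolution, dominated by the contact-edge singularity; mirror-image
  placements agree within 1% only once the near size reaches ~0.1 mm.
* **Thin-layer rim.** Stria interface nodes on the sector rim are shared
  (jump pinned to zero at the rim line), a standard and benign thin-layer
  approximation.

## A worked sweep

```{r example, eval = FALSE}
params <- cochlea_params()
array  <- electrode_array_spec()
cond   <- conductivity_table()

prof <- run_insertion_depth_profile(params, array, cond)
plot_depth_profile(prof)

ray <- make_proximity_ray(params, array, axis = "x", n_positions = 8)
sweep <- run_proximity_sweep(params, array, cond, ray)
plot_proximity_profiles(sweep, axis = "x")

sens <- run_conductivity_sensitivity(params, array, cond)
sens$normalized_deviation   # < 0.01 at defaults
```

The numbered scripts under `analysis/` run the full study (geometry and
grid, sequential insertion, proximity sweeps, sensitivity, verification) and
write tidy CSV results with JSON provenance sidecars under `results/`.
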