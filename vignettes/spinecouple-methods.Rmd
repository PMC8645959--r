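---
title: "Coupled musculoskeletal and finite element simulation of lumbar fixation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled musculoskeletal and finite element simulation of lumbar fixation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinecouple)
```

## Purpose and scope

`spinecouple` compares two ways of loading a thoracolumbar spine model
with an L1–L5 posterior fixation: the *simplified* convention of a pure
bending moment on the most cranial vertebra, and a *realistic* load set
of muscle forces plus gravity obtained from an inverse-static
musculoskeletal (MSK) stage.  The package contains everything needed to
run this comparison on a synthetic, parametric anatomy: the anatomy and
muscle generator, the structural solver, the MSK stage, the fixation
construct, and the coupling pipeline with its consistency checks.

The point of the synthetic anatomy is to make the *coupling logic*
testable end to end.  Absolute stress values depend on geometry and
material calibrations that are outside the scope of a desk-scale model;
what the pipeline is designed to reproduce are the consistency
properties (realistic kinematics tracking the simplified kinematics;
FE/MSK agreement of the boundary load) and the directional finding that
muscle-based loading raises implant stresses.

## Coordinate conventions and units

Right-handed global frame: X anterior, Y left, Z cranial.  Positions in
mm, forces in N, moments in N·mm (reports print N·m), stresses in MPa.
Motion axes: flexion +Y, extension −Y, lateral bending left −X / right
+X, axial rotation +Z.  Angles are radians internally and degrees at
every interface.

## The synthetic anatomy

`build_default_spine()` stacks T10…L5, the sacrum and a pelvis along a
sagittal curve defined by per-level tilt angles (a mild standing lordosis
of ~35° below a beginning thoracic kyphosis; the defaults are mid-range
textbook dimensions, every one of them a config value).  Each body is a
rigid frame carrying landmarks: endplate centres, pedicle entry points
(35 mm posterior, ±16 mm lateral), spinous tips, transverse processes.
One joint centre sits at mid-disc between consecutive bodies; two
sacroiliac joints (SIJ) connect sacrum and pelvis at ±35 mm laterally.

`build_muscle_set()` generates 66 straight-line fascicles in the nine
trunk muscle groups of the thoracolumbar MSK literature — transversus,
spinalis, semispinalis, erector spinae, obliquus internus and externus,
psoas major, multifidi, quadratus lumborum — bilaterally, with maximum
forces `f_max = PCSA × 90 N/cm²`.  Three architectural choices matter:

* the superficial erector spinae is *thoracic-dominant* (pelvis to
  T10–T12 slips at 4.8 cm², lumbar slips at 2 cm²), because the large
  superficial extensors bridge the lumbar spine rather than loading each
  lumbar vertebra equally;
* the oblique abdominals and transversus run along the abdominal wall,
  well anterior (55–72 mm) of the vertebral bodies, which is where trunk
  flexion moment is actually generated — attachment lines hugging the
  spine cannot flex the upper cuts with plausible forces (verified by a
  non-negative least-squares feasibility check during development);
* slip counts (2–6 per group per side) are a minimal defensible
  architecture, not a subject-specific one.

A coverage invariant is enforced at build time: every intervertebral
joint must be crossed by fascicles with both positive and negative
moment-arm components about the flexion–extension and lateral-bending
axes, otherwise recruitment is infeasible and the generator aborts with
the offending joint and axis.

## The structural (FE) model

Vertebrae are rigid nodes with 6 DOF under small-rotation kinematics.
Elements:

* **Bushing joints** — one 6×6 diagonal spring per joint in the joint
  frame.  Rotational stiffness 1.0–1.8·10⁵ N·mm/rad per axis (giving
  segmental ROMs of 2.4–4.3° at 7.5 N·m, within in-vitro ranges),
  translational stiffness 800 N/mm in shear and 3000 N/mm axially
  (mid-range lumbar functional-spinal-unit values; these also govern how
  rigid an instrumented segment is, because the construct moves the
  centre of rotation toward the rods and the disc then resists by
  translation).  SIJ: 5·10⁶ N·mm/rad per joint (~175 N·m/° combined,
  mid-range of published standing load-transfer stiffness) and 5000 N/mm
  translational.
* **Ligaments** — one tension-only spring per level between spinous
  tips (10 N/mm beyond 1 mm slack): a deliberately small nonlinear
  element that makes the flexion response direction-dependent, as real
  posterior ligaments do.  The force–elongation curve is piecewise
  linear and monotone; force is identically zero in compression.
* **Beams** — 2-node Euler–Bernoulli elements with 6 DOF per node for
  the instrumentation (titanium, E = 110 GPa, ν = 0.3; rods ⌀5.5 mm,
  screws ⌀6 × 45 mm).  Shear deformation is neglected; the exposed screw
  segments are short but stress recovery at their ends is exact for the
  end-loaded case, which is the loading they see.

The pedicle screws are modelled as a beam chain head–entry–tip with the
shank (entry and tip nodes) rigidly tied to the vertebra — a bonded
screw–bone interface — so only the 12 mm exposed head segment is
compliant.  Rod polylines pass through the ipsilateral screw heads
(shared nodes, i.e. welded screw–rod connections) with two elements per
span.  Rigid ties are master–slave eliminations, so the assembled system
is reduced exactly.  The pelvis (acetabula) is fully fixed.

`solve_static()` runs Newton iteration on the residual; only the
ligament tension state is nonlinear, so intact solves converge in 1–3
iterations to ‖r‖ ≤ 10⁻⁶ N + 10⁻⁸·‖f‖.  Singular reduced stiffness
(a mechanism) is reported with the number of unconstrained modes;
residual growth over three consecutive iterations aborts the solve.

Two recovered quantities drive everything downstream:

* **ROM** — the relative rotation of the cranial body with respect to
  the caudal one, projected on the motion axis in the joint frame;
  positive along the motion direction.  Being relative, it is invariant
  to rigid translations.
* **Transmitted load across a cut** — the force and moment the part
  above a joint carries down through every crossing element, reported
  about a reference point.  Under an intact pure moment this equals the
  applied moment at every cut to machine precision (an exact analytic
  property used as a solver test), and it is the quantity compared
  between FE and MSK at the T10 boundary.

Beam von Mises stress uses the slender-member recovery
σ = |N|/A + √(M_y² + M_z²)·(d/2)/I, τ = |T|·(d/2)/J,
σ_vM = √(σ² + 3τ²), maximised over element ends per component.  Percent
of yield is reported only when a yield stress is configured, since no
single value is canonical for titanium alloys.

## The musculoskeletal stage

**Calibration.**  For every joint and axis the MSK rotational stiffness
is the FE secant `k = M_local / θ_local` at 7.5 N·m, taken from the
pure-moment solve whose dominant component is that axis — flexion and
extension separately, because the tension-only ligaments make the
sagittal response direction-dependent.  Coupling and translational terms
are discarded, matching the linear moment–rotation idea of rigid-chain
trunk models.  A joint the FE reports as rigid (< 10⁻⁴ °) is assigned a
configurable ceiling (10⁶ N·mm/deg) with a warning.

**Imposed motion and inverse statics.**  The stage-A relative rotation
vectors are imposed per cut (fused joints forced to zero).  The muscles
must supply, about each free intervertebral cut, the passive moment
`K θ` plus the moment of the gravitational loads above the cut.  Two
structural choices:

* *The sacrum–pelvis connection carries no recruitment constraint.*  The
  rigid-chain trunk models this stage emulates treat the sacrum as part
  of the grounded pelvis segment, and the muscle set contains no
  SIJ-only actuators, so demanding the full moment balance there is
  structurally infeasible for non-negative forces (confirmed by NNLS
  during development).  The elastic SIJs remain in the FE model and
  their simplified-vs-realistic consistency is *measured*, not imposed.
* *Gravity is on by default.*  The compressive body weight carried by
  the trunk muscles is precisely what distinguishes realistic from
  pure-moment loading, and it is what makes muscle-based loading raise
  the implant stresses; with gravity disabled (config switch) the
  comparison degenerates to nearly equivalent load paths.  Defaults: 21
  kg above T10 applied as the T10 boundary reaction, 1.6–2.0 kg trunk
  slices per modelled level, with centres of mass placed so the combined
  trunk gravity line passes just anterior of the lumbosacral junction —
  a balanced standing posture, which is also why the residual gravity
  moments about the joints stay in the physiological few-N·m range.

**Recruitment.**  min Σ (fᵢ/f_max,ᵢ)³ subject to `A f = b`, `f ≥ 0`,
with the cubic exponent exposed in config (any p > 1 keeps the problem
strictly convex on the feasible set, hence the solution unique).  The
solver is a primal–dual interior-point Newton method on the perturbed
KKT system, in variables normalised by `f_max` and by ‖b‖; it converges
in ~20 iterations to 10⁻¹⁰ scaled residuals.  Every solution must pass
an *independent equilibrium certificate* — brute-force summation of the
fascicle line-of-action moments about every constrained cut, not the
optimizer's own constraint values — to 10⁻⁶ relative.

**Fused variant.**  The joints interior to the instrumented block are
constrained to zero imposed rotation and dropped from the moment
balance: the rigid connection transmits force and moment in full, so the
muscles owe nothing there (and whatever they exert across the block is
exactly the extra load the construct must carry — the mechanism behind
the stress increase).

**The T10 boundary.**  With T10 the cranial end of the chain, the
"reaction at the T10 upper endplate" is reported by both models as the
load transmitted across the most cranial joint (T10/T11), expressed
about the endplate centre; the applied boundary loads in stage C are
the weight of the body above T10.  The boundary *translation* cannot be
predicted by a rigid chain at all, so the coupling obtains it from the
calibrated elastic chain itself: a load-controlled FE solve under the
recruited loads yields the T10 translation that the
displacement-controlled realistic solve then prescribes.  Prescribing a
consistent translation keeps the boundary constraint force near zero —
the resolution of the over-determination inherent in combining
prescribed translations with applied reaction loads — and the residual
constraint force is always reported.  (A per-cut translational
compliance calibration by force probes was tried first and abandoned: a
probe force at T10 unavoidably adds lever moments at the lower joints
and contaminates the measured compliance.)

## The pipeline and its consistency gates

`validate_and_report()` runs stages A→B→C for the requested motions and
variant and checks, with config-overridable bounds:

* max per-joint |ROM_realistic − ROM_simplified| ≤ 0.7° (intact) or
  0.3° (instrumented);
* max relative difference of the T10 reaction moment (motion-axis
  component; the vector-norm version is reported secondarily) ≤ 3.5 %.

Axial rotation is available under simplified loading (it calibrates the
torsional stiffness) but excluded from stages B/C.  On the default
model the intact ROM differences are ≤ 0.21° (lateral bending ≤ 0.001°),
the instrumented ones ≤ 0.28°, and the T10 moment agreement is at
solver precision.  The residual ROM differences are physically
interpretable: muscle compression slackens the posterior ligaments
relative to the calibration state (the MSK stiffness does not account
for compressive loading), and the uncontrolled cuts — the SIJs and the
fused block interior — pick up the small gravity and co-contraction
moments the muscles are not asked to balance.

Determinism: there is no randomness anywhere in the default pipeline;
two runs from the same config produce byte-identical CSV reports.  The
config seed exists for user-driven perturbation studies.

## Problem sizes and runtime

The assembled intact system has 60 nodal DOF (10 rigid bodies), the
instrumented one ~230 including beam nodes before master–slave
reduction; all linear algebra is dense base R.  A full four-motion
variant run — 5 calibration solves, 4 recruitments, 4 free-boundary
pre-solves, 4 realistic solves — takes well under a second, and the
complete test suite a few seconds.

## What the synthetic model does and does not show

Passing the consistency gates demonstrates that the coupling logic is
self-consistent and that the directional finding (realistic ≥ simplified
hardware stresses for all four motions once bodyweight compression is
carried by the muscles) is reproduced on a plausible anatomy.  It does
not validate absolute magnitudes: the synthetic model has lumped joints
instead of continuum discs, straight-line fascicles without wrapping, a
bonded screw interface, no ribcage, and textbook-average geometry.  Two
further known limitations: axial rotation under posterior-only fixation
remains relatively mobile (~0.26° at fused levels, vs < 0.1° for
flexion–extension and lateral bending) because without transverse
connectors the softest torsional path is screw-head/rod bending — one
reason axial rotation is excluded from the realistic comparison; and the
SIJ response under realistic loading is an outcome, not a controlled
quantity, so its consistency depends on the standing posture being
gravitationally balanced.
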