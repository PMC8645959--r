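# spinecouple

Coupled musculoskeletal–finite-element simulation of the thoracolumbar
spine, for comparing **simplified loading** (pure bending moments) with
**realistic loading** (muscle forces) in terms of segmental motion and the
stresses in posterior fixation hardware.

## The problem

Spinal implants — pedicle screws and rods — are usually evaluated *in
vitro* and *in silico* under pure moments of ±7.5 N·m applied to the most
cranial vertebra, because pure moments are reproducible and transmit
unchanged along an unloaded spine.  A standing patient, however, loads the
spine through muscle tension and body weight.  `spinecouple` implements a
three-stage coupling that quantifies what the simplification hides:

* **Stage A (simplified):** a static finite-element model of T10–pelvis —
  rigid vertebrae connected by generalized bushing joints (lumped disc +
  facet + ligament stiffness), tension-only posterior ligament springs,
  and an optional L1–L5 screw/rod construct of titanium beam elements —
  is solved under a 7.5 N·m pure moment; per-joint ranges of motion (ROM)
  are extracted.
* **Stage B (musculoskeletal):** the stage-A rotations are imposed on a
  rigid-chain trunk model whose joint rotational stiffness is calibrated
  to the FE secant behaviour, `k = M / θ` at 7.5 N·m, per axis and signed
  direction.  Inverse statics gives the net moment the muscles must supply
  about every intervertebral joint (including gravitational segment loads
  for the standing posture), and muscle redundancy over 66 fascicles in 9
  trunk muscle groups is resolved by static optimization,

      min Σᵢ (fᵢ / f_max,ᵢ)³   s.t.   A f = b,  f ≥ 0,

  solved by a primal–dual interior-point method and verified by an
  independent brute-force moment summation.
* **Stage C (realistic):** the recruited forces are applied to the FE
  model as concentrated loads along each fascicle's line of action, the
  T10 boundary carries the reaction loads and the predicted translation,
  and the pure moment is removed.  ROMs and maximal von Mises stresses in
  the screws and rods are recovered (`σ = |N|/A + |M| (d/2)/I`,
  `τ = |T| (d/2)/J`, `σ_vM = √(σ² + 3τ²)`).

The coupling is *validated* by its own consistency: stage-C ROMs must
track the stage-A ROMs that stage B was fed (≤ 0.7° intact, ≤ 0.3°
instrumented), and the T10 reaction moment must agree between the MSK and
FE solutions (≤ 3.5 %).

All anatomy is synthetic and parametric (a built-in generator with
configurable vertebral dimensions, sagittal curvature, joint stiffnesses,
muscle attachments and strengths); no external data are required.

## Worked example

```r
library(spinecouple)

cfg <- pipeline_config(fixation = fixation_config(yield_stress = 780))
rep <- validate_and_report(cfg, "instrumented", motions = c("extension", "flexion"))
print(rep)
#> Coupling report (instrumented): motions extension, flexion
#>   max |ROM realistic - simplified| = 0.273 deg (bound 0.3 deg)
#>   max T10 reaction-moment relative difference = 6.41e-11 % (bound 3.5 %)
#>   max implant stress increase (realistic - simplified) = 74.4 MPa
#>   consistency bounds hold
```

The instrumented model keeps its fused levels nearly motionless in both
loading modes (|ROM| ≤ 0.2° at L1–L5) while the free joints move by
2.7–3.6°, and the realistic ROMs stay within 0.3° of the simplified ones
— the two loading modes are kinematically equivalent, as intended.  The
hardware stresses are not:

```r
sd <- rep$stress_delta
sd[sd$motion == "extension", c("component", "delta_MPa", "delta_pct_yield")]
#>        component delta_MPa delta_pct_yield
#> 1       rod_left     74.35           9.532
#> 3  screw_L1_left      6.58           0.843
#> 11 screw_L5_left     21.11           2.706
#> ...
```

Under realistic loading the posterior rods in extension carry 87.8 MPa
against 13.4 MPa under the pure moment (+74 MPa, 9.5 % of the configured
yield stress), and every screw stress increases as well: the muscle and
body-weight compression that pure moments omit loads the construct.
Pure-moment testing **underestimates** hardware stresses.

A thin CLI wraps the same pipeline:

```sh
Rscript exec/spinecouple run --model instrumented --motion all --out out/
Rscript exec/spinecouple validate            # both variants, exits non-zero
                                             # if a consistency bound fails
```

Outputs are plain CSVs (`rom_comparison.csv`, `stress_comparison.csv`,
`muscle_forces.csv`, `t10_moment_comparison.csv`) plus a run-metadata
record.

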