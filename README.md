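# rwdirect

Directional sensitivity of bone-conduction (BC) stimulation at the round
window, as a tested R pipeline.

When a bone-conduction implant drives the otic capsule directly — the bony
shell of the inner ear — the cochlear response depends on the *direction* of
the stimulating force, not just its magnitude. `rwdirect` implements the
full analysis chain used to quantify that directional sensitivity from
frequency-domain finite-element displacement fields:

1. **Direction parametrization.** A stimulation frame (origin + versors
   x̂₀₀, ŷ₀₀, ẑ₀₀) fixes the primary direction ẑ₀₀; any force direction is
   ẑ_αβ = **B**(β about ŷ_α0) · **A**(α about x̂₀₀) · ẑ₀₀ with both rotation
   matrices in Rodrigues form, α, β ∈ [−90°, 90°].
2. **Rigid edge motion.** The round-window (RW) bony edge ring (48 nodes,
   16 disjoint node triples) carries complex z-displacements; each triangle's
   rigid motion (w, γ, φ) solves w_s = w + γ·y_s − φ·x_s exactly, and the
   triple is averaged over the triangles → (w̄, γ̄, φ̄).
3. **Volume displacement.** The membrane mesh (218 quads → 436 triangles)
   integrates the relative deflection Δw = w_z − (w̄ + γ̄y − φ̄x):
   V = Σ_t (A_t/3)(Δw_A + Δw_B + Δw_C), a complex mm³ quantity.
4. **Directional criteria.** Per frequency f, amplitudes |V| and |w̄| are
   normalized by their grid maxima; weights μ_f = 1 − min/max measure how
   much direction matters; the criterion is the μ-weighted mean of the
   normalized maps over the 17-frequency one-third-octave ladder
   (0.2–10 kHz).
5. **Extremum refinement.** Coarse 15°-grid extremes are refined through a
   9-node biquadratic Lagrangian interpolant on the 3×3 neighbor stencil
   (symmetry-completed at the ±90° boundary).

A compact harmonic finite-element solver (8-node hexahedra, hysteretic
damping via complex modulus E(1+iη), consistent mass, lumped surface and
implant masses) plus a synthetic-field generator provide fully reproducible
inputs: a toy temporal-bone block with fluid cavity and membrane window for
end-to-end runs, and planted-ground-truth fields for parameter-recovery
tests. The package is aimed at auditory-biomechanics researchers
post-processing their own FE exports, and at anyone who wants a transparent,
tested reference for the RW volume-displacement bookkeeping.

## Worked example

```r
library(rwdirect)

fr <- stimulation_frame()        # packaged frame at the otic-capsule site
fr
#> <rw_frame>
#>   origin (mm): -45.92   6.24 -25.28
#>   x_hat:  0.0039993 -0.9178399  0.3969307
#>   y_hat: -0.269857 -0.383198 -0.883366
#>   z_hat:  0.962892 -0.103582 -0.249218

v <- direction_vector(fr, -45, 25)   # VD-criterion maximum direction
round(v, 4)
#> [1]  0.4458 -0.6999 -0.5581
angle_between(v, direction_vector(fr, -49, 1))
#> [1] 24.30908      # the two "good" directions are only 24 degrees apart

fx <- make_rw_fixture()          # 48-node ring + 218-quad membrane, r = 1.5 mm
fl <- make_field(fx, field_truth(w = 0.1 - 0.05i, gamma = 0.02i, phi = 0.01,
                                 profile = "piston", d = 0.3 + 0.4i))
rmot <- ring_motion(fx$ring, fl$ring_wz)
rmot
#> <rw_ring_motion>  w = 0.1-0.05i mm, gamma = 0+0.02i rad, phi = 0.01+0i rad
total_vd(fx$membrane, fl$membrane_wz, rmot)
#> <rw_vd>  V = 2.120575+2.827433i mm^3  |V| = 3.534292  phase = 53.1301 deg
```

The fitted ring motion reproduces the planted rigid field exactly, and the
piston deflection d = 0.3+0.4i mm over the membrane area A = 7.0686 mm²
gives V = A·d — the rigid part of the motion drops out of the volume
displacement by construction.

End-to-end on the toy model:

```r
td <- tempfile()
run_simulate(list(grid = list(step = 45),
                  frequencies = c(500, 1000, 2000, 4000, 8000)), td)
tab <- run_analyze(td)              # ring motion + V per (direction, frequency)
res <- run_criteria(tab)            # weights, criterion maps, refined extremes
res$V$extremes
```

## Layout

- `R/frames.R` — frames, Rodrigues rotations, (α, β) parametrization
- `R/ring-kinematics.R` — edge-ring triangulation and rigid-motion fit
- `R/volume-displacement.R` — membrane mesh, signed areas, V
- `R/criteria.R` — normalization, weights, weighted-sum criteria, B81 force
- `R/refine.R` — biquadratic stencil refinement of grid extremes
- `R/harmonic-fe.R` — hex8 harmonic solver (assembly, sweep)
- `R/synthetic.R` — fixtures, planted fields/surfaces, toy bone model
- `R/pipeline.R` — simulate/analyze/criteria stages and the CSV container
- `vignettes/directional-sensitivity.Rmd` — methods and design notes
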