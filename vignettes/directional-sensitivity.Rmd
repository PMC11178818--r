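---
title: "Directional sensitivity of bone-conduction stimulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional sensitivity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwdirect)
```

## The problem

A bone-conduction implant seated directly on the otic capsule excites the
inner ear through bone vibration. Because the petrous temporal bone is
heterogeneous in mass and stiffness and the excitation point is close to the
cochlea, the cochlear response depends on the *direction* of the harmonic
stimulating force. `rwdirect` quantifies that dependence with two mechanical
criteria evaluated at the round window (RW): the averaged displacement of
the bony RW edge perpendicular to the window, and the fluid volume
displacement (VD) of the RW membrane relative to the rigid motion of its
edge. Both are complex, frequency-resolved quantities computed per force
direction.

## Direction parametrization

The stimulation frame is a right-handed versor triple (x̂₀₀, ŷ₀₀, ẑ₀₀) at
the excitation site; ẑ₀₀ is the primary direction. A force direction is

  ẑ_αβ = **B**(β about ŷ_α0) · **A**(α about x̂₀₀) · ẑ₀₀,

with both matrices in Rodrigues axis-angle form and α, β ∈ [−90°, 90°]
sampled every 15° (13 × 13 = 169 directions). Angles are degrees throughout
the public interface; radians appear only inside trig calls, because every
number a user meets in this domain is printed in degrees.

Versors printed to three decimals are not exactly orthonormal (errors up to
~2·10⁻³). `frame()` restores an exact triad by one Gram–Schmidt pass
anchored on x̂₀₀; the test suite asserts the repair moves each versor by
less than the rounding that broke it. Anchoring on x̂₀₀ keeps the α-rotation
axis exactly as printed, which is the axis the parametrization applies
first.

Two algebraic identities follow from the rotation algebra and are asserted
numerically (on a 5° lattice) rather than assumed:

* `direction_vector(α+180°, β+180°)` equals `direction_vector(α, −β)`
  *with the same sign* — the two parameter pairs name the same force, so
  amplitudes and phases coincide (`symmetry_image()` records
  `phase_sign = +1` as derived from the vectors);
* `direction_vector(α+180°, β)` equals `−direction_vector(α, −β)` — the
  antipodal force, equal amplitudes with reversed phase under a linear
  model.

The inverse map `angles_from_direction()` resolves the ±v ambiguity by
preferring the representative with α ∈ [−90°, 90°], then the one with
v·ẑ₀₀ ≥ 0. At the gimbal poles |β| = 90° the α angle is undefined; the
function returns α = 0 with an explicit `degenerate` flag (checked on the
input vector before the ±v preference, where numerical noise could
otherwise flip the pole sign) so downstream maps remain plottable.

## Rigid motion of the RW edge

The edge ring nodes are sorted by polar angle in the RW plane and grouped
into consecutive disjoint triples — 48 nodes into 16 triangles in the
canonical configuration. How triples are formed is a genuinely open choice;
disjoint consecutive grouping is consistent with 48/3 = 16 and with
adjacent-triangle sketches of such rings, and the grouping is injectable
(`build_ring(..., triangles = )`) for sensitivity checks. The averaged
motion is provably independent of the grouping for globally rigid fields,
which the tests assert with rotated and permuted groupings.

Each triangle's small-rotation rigid model w_s = w + γ·y_s − φ·x_s is
inverted with the explicit 3×3 inverse (denominator
(y_k−y_i)x_j + (y_j−y_k)x_i + (y_i−y_j)x_k); triangles with |denominator|
< 10⁻¹² mm² are rejected by name. Complex arithmetic carries the separate
real/imaginary channels of the frequency domain in one pass — the model is
linear, so this is exactly equivalent to two real solves, and a test checks
the two-channel equivalence term by term. The small-rotation assumption is
inherited as-is; no finite-rotation correction is applied.

## Volume displacement

Membrane quads (A,B,C,D) split along the A–C diagonal into (A,B,C) and
(A,C,D). The projected triangle area is the signed shoelace half-sum; the
canonical winding is counterclockwise viewed from +z (toward the cochlea),
so that outward deflection yields positive V. The area convention is not
forced by the integral itself — a sign convention had to be chosen — and
meshes arriving with the opposite winding are re-wound on load with a
notice. The alternative B–D diagonal is available as a switch; it changes V
only for non-planar bilinear fields. Node z-coordinates are ignored in the
area projection even for curved membrane fixtures, matching the
projection-onto-xy definition of the integral.

V = Σ_t (A_t/3)(Δw_A + Δw_B + Δw_C) with Δw = w_z − (w̄ + γ̄y − φ̄x). Three
properties anchor the implementation and are tested at stated tolerances:
adding any complex rigid field to membrane and ring simultaneously leaves V
unchanged (to 10⁻¹⁰ relative); a uniform piston d gives V = A_total·d; and
arbitrary nodal fields match a recursive 4-way subdivision oracle that
integrates the linear interpolant independently.

## Weighted directional criteria

Per frequency, amplitudes are normalized by their grid maximum and weighted
by μ_f = 1 − min/max ∈ [0, 1]: μ near 1 means direction matters at that
frequency, μ = 0 means it does not and the frequency drops out of the
criterion sum. The criterion is Σ_f n(α,β,f)·μ_f / Σ_f μ_f, computed for
|V| and |w̄| independently. "Amplitude" of the averaged edge motion is
defined as the modulus of the complex mean w̄ (real and imaginary parts
averaged first); the reduction order is a design choice the tests pin down.
A fully direction-independent surface (Σμ = 0) raises an explicit error
rather than returning a silent fallback — a criterion of undefined weights
has no meaning.

Grid argmax/argmin ties are broken deterministically by smallest
(|α|, |β|, α, β) in lexicographic order, with a warning; continuous data
never tie, but synthetic and degenerate inputs can.

The B81 helper converts transducer output force levels to newtons via
F = (2.5/2.83)·10⁻⁶·10^(OFL/20), the stepped-sine calibration of that
transducer at 2.5 V peak-to-peak relative to its 1 V-rms rating.

## Extremum refinement

The criterion surface is sampled every 15°, too coarse to localize
extremes. Around a coarse extremum, the 3×3 stencil of neighbor values
defines a biquadratic through the tensor product of 1-D quadratic Lagrange
bases on {−1, 0, 1}. The interpolant's extremum over the biunit square is
found by dense sampling at local step 0.005 followed by one Newton polish,
then clamped to the square. Pure Newton alone was rejected: a biquadratic
can have a saddle at the stencil center, and dense-first makes the
refinement unconditionally robust at negligible cost (401² evaluations of a
separable polynomial). Clamping rather than extrapolation is used for
refined extremes that press against the stencil edge; such results carry a
`boundary` flag since they usually mean the coarse extremum was
misidentified.

Stencils crossing the ±90° sampling boundary are completed through the
direction symmetry: β ± 180° names the same force axis, and α ± 180° with
β → −β names its antipode, so response *amplitudes* — all the criteria use
— are equal either way. `wrap_angles()` applies these reductions and the
tests verify wrapped stencil entries against direct evaluation.

## The toy harmonic FE solver

The solver exists to exercise the pipeline end to end, not to reproduce any
anatomy. It implements 8-node hexahedra with 2×2×2 Gauss quadrature,
consistent mass, and hysteretic (rate-independent) damping via the complex
modulus E(1+iη) — the standard frequency-domain convention when a material
damping model is otherwise unspecified; η defaults to 0.05 per material and
is a config input. The harmonic operator K(1+iη) − ω²M is factorized
densely (LAPACK complex LU) once per frequency and shared across all force
directions as a multi-RHS solve; damping is non-proportional across
materials, so modal superposition was not used. Internal units are SI;
configs accept mm/g and convert on construction, because the domain's
geometry numbers are printed in mm and grams.

The toy temporal bone is a 20 mm block (8³ cells, ~2 000 free DOFs) with an
interior fluid cavity, a soft membrane column spanning the cavity wall so
the window can bulge toward the free outer surface, a fixed lateral face
standing in for the connection to the rest of the skull, soft-tissue surface
mass (2.5·10⁻³ g/mm²) lumped on the outer faces, and a 0.16 g implant mass
split equally over the attachment-circle nodes, with the force split the
same way (the coupling constraint type is a genuine unknown; a rigid-spider
coupling is out of scope). The force sign convention is +ẑ_αβ; amplitudes
are unaffected by this choice, phases would flip. The cochlear fluid is a
nearly incompressible elastic solid (ν = 0.499, E from the water bulk
modulus) rather than an acoustic formulation — one element type keeps the
solver small, at the cost of volumetric locking stiffening the fluid; a
stated limitation, acceptable for a pipeline exerciser.

Physics anchors tested: exact static uniaxial patch test; fixed-free rod
resonance within 2% of (1/4L)√(E/ρ); linearity; reciprocity of the undamped
operator; mass conservation including surface and attachment terms; and a
single-element stiffness check against an independently coded 3-point-Gauss
assembly (exact agreement is expected only for affine elements, where the
integrand is polynomial; distorted elements are checked through the
constant-strain patch condition, which holds under any quadrature).

## Synthetic data: what it does and does not emulate

Generators are pure functions of (config, seed). The RW fixture is a
circular 48-node ring with a structured quasi-circular membrane patch: the
n_quads square cells of a regular grid nearest the origin. This template
reaches *any* quad count exactly — 218 included — at the cost of a jagged
patch boundary, which none of the downstream quantities depend on (areas
and fields are evaluated per element). Planted fields put an exact complex
rigid motion on the ring and rigid + profile·d (+ optional complex Gaussian
noise, independent Re/Im, the simplest adequate robustness model) on the
membrane. Planted response surfaces follow
c(f)·(ε + max(0, ẑ_αβ·d*)^p), whose continuum argmax is the planted
direction; defaults ε = 0.05 and p = 2 give map curvature on which coarse
search + refinement recovers the planted direction within 1.5°, the
recovery bound the tests enforce.

What passing these tests shows: the bookkeeping chain — fit, integral,
normalization, weighting, refinement — is exact or convergent on fields
whose ground truth is known. What it does not show: anything about a real
temporal bone. The synthetic fields have no spatial correlation structure,
no resonances, and the toy geometry is deliberately non-anatomical, so
specific extreme directions from the toy model carry no anatomical meaning.

## Pipeline and container format

`run_simulate` → `run_analyze` → `run_criteria` compose the stages; each is
deterministic given (config, seed), validates its inputs before computing
(unknown config keys are rejected), and produces results identical to
calling the library functions directly — a property the tests assert
row-for-row. The field container is a directory of plain CSV files plus a
`manifest.json` with a config hash (timestamps excluded, so reruns hash
identically), seed and package version. A single binary container file
would be more compact, but R bindings for such formats are not part of this
package's minimal dependency set, and text files keep containers
diff-able and portable; the layout (directions, frequencies, node tables,
long field table) is documented in `read_container()`.

Phases are reported in degrees in (−180°, 180°], amplitudes in mm (edge)
and mm³ (VD), the units of the domain's figures.

## Problem sizes and tolerances

The test suite runs the full 169-direction × 17-frequency criteria path on
synthetic surfaces (instantaneous) and a reduced 5×5-direction ×
5-frequency sweep through the toy FE model (~2 000 DOFs, seconds per
frequency) — large enough to exercise every branch, small enough to run
anywhere. Exactness claims (rigid-motion fit, piston V, criteria algebra)
are tested at 10⁻¹⁰–10⁻¹⁴; physics claims (resonance, recovery) at their
stated engineering tolerances (2%, 1.5°, 0.05°).

## Known limitations

* Only the z-component of the RW edge motion is fitted; in-plane edge
  motion is ignored by the criterion's definition.
* Small-rotation kinematics throughout.
* The toy fluid is an elastic stand-in; no acoustic-structure coupling, no
  basilar membrane, no middle/outer ear.
* The membrane surface is treated as a single mid-surface; hexahedral
  membrane stacks with distinct fluid/bone faces are not modeled.
* Refinement is strictly local (3×3 stencil); no global surrogate fit.
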