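---
title: "Methods: phantom-based validation of a murine bone-fragility analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based validation of a murine bone-fragility analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonefrag)
```

# Scope and design

`bonefrag` re-implements, as reusable and tested R functions, the
quantitative chain used in preclinical mouse studies of diabetic bone
fragility: micro-CT morphometry of trabecular and cortical bone, voxel-based
micro-finite-element (micro-FE) estimation of vertebral failure load,
load-displacement curve analysis including crack-initiation toughness of
micro-notched femora, CPMG T2 relaxometry for matrix bound water, and the
branching two-factor statistical procedure applied to end-point outcomes.

Animal-scan data for such studies are typically available only on request,
so every stage here is validated against *synthetic phantoms with
analytically known ground truth*: a voxelized annulus stands in for the
femur mid-diaphysis, an orthogonal rod lattice for trabecular bone, an
elliptical shell plus lattice for a vertebral body, piecewise structural
models for bending curves, multi-exponential decays for CPMG echo trains,
and parametric 2 x 3 cohorts for the statistics. What passing tests show is
therefore *internal correctness* — each estimator recovers the quantity it
is defined to measure, on geometry where that quantity is known in closed
form — not agreement with any scanner's or vendor tool's output on real
bone, which carries beam hardening, partial-volume gradients, anisotropic
noise and anatomy that no phantom here emulates.

# Phantoms and their conventions

A voxel belongs to a phantom solid iff its *center* lies inside the analytic
surface; this rule is unambiguous and converges under refinement, and the
voxel-count quantities it produces (BV/TV, per-material counts, porosity
realized by pore sampling) are recorded as ground truth alongside the
closed-form ones (areas, moments, thicknesses). The default phantom voxel
size is 12 um — coarser than the 6 um of the ex vivo protocol the chain
mirrors — to keep routine runs at desk scale; convergence-sensitive checks
refine to 6 um locally. Acquisition noise is additive Gaussian on the
calibrated density or signal; a Rician option exists for CPMG magnitude
data but is off by default, since at the protocol's signal-to-noise ratio
the two are indistinguishable. The protocol gives no instrument noise
level, so phantom noise defaults are free parameters, not calibrated
values. Every generator draws from a private stream seeded by
`(seed, operation name)`, so adding a generator never perturbs another's
draws, and identical calls are byte-identical.

The bending-curve generator needs one non-obvious convention. Its ground
truth records stiffness, yield, ultimate force, post-yield displacement and
work *as defined by the analysis criteria* (0.9-secant yield on the
continuous model, located by root finding; work by exact quadrature), next
to the raw model breakpoints. A recovery contract of "within 1%" is only
meaningful against criterion-consistent truth: the 0.9-secant point sits
measurably beyond the kink where the model leaves linearity (about 3% in
force for the default hardening), and when the secant never drops below
90% of stiffness before the peak, both generator and analyzer place yield
at the ultimate point.

The cohort generator's default cell locations and spreads are patterned on
the published end-point blood-glucose medians and interquartile ranges of
the six cells of the canagliflozin x glucose-group design, with the
published group sizes; location-scale Gaussian, median-preserving lognormal
and scaled-t families are available to exercise the non-parametric branches.

# Morphometry

Segmentation is a truncated Gaussian filter (vendor-style sigma/support
pair, in voxels, zero-phase with reflection padding) followed by a global
threshold in mg HA/cm^3. Tissue mineral density is averaged after a
Euclidean surface peel (default 2 voxels) to limit partial-volume
contamination; on phantoms whose surface voxels carry depressed density the
peel provably raises TMD back to the core value.

Local thickness (Tb.Th, Tb.Sp, Ct.Th) uses the sphere-fitting definition:
the thickness at a point is the diameter of the largest inscribed sphere
containing it, computed from the exact 3D Euclidean distance transform with
sphere centers restricted to the distance ridge. The volume border is open
(structures continue past it), so thin analysis slabs do not truncate
spheres. The discrete estimate carries a surface bias of at most one voxel
(by construction it rounds up); the tests budget for this explicitly.

Tb.N defaults to the direct mid-axis method: extract the distance ridge of
the bone phase, measure the mean spacing between mid-axes by sphere fitting
on their complement, and invert. On the spec'd rod lattice (60 um rods at
300 um pitch) this recovers 1/pitch within ~5% across 6-15 um voxels. The
plate-model alternative 1/(Tb.Th + Tb.Sp) is behind a flag, never the
default. Note a geometric subtlety the lattice exposes: sphere-fit Tb.Sp on
a 3D rod lattice is *larger* than the nominal gap (pitch - diameter),
because the largest marrow sphere sits on the cell diagonal; the tests
assert the documented band rather than the nominal value.

Connectivity density is (1 - chi)/TV with chi the Euler characteristic of
the 26-connected bone phase (6-connected background duality, which avoids
topological paradoxes), computed by counting vertices, edges, faces and
cubes of the union-of-closed-cubes complex; this is exact, and the suite
checks it against an independent exhaustive counter on random volumes up to
20^3 and against the lattice graph's first Betti number.

Cortical metrics follow the slice-wise 2D convention averaged over the
slab: the periosteal contour is the boundary of the morphological closing
of the slice mask (closing radius configurable); Tt.Ar is the filled area,
porosity is pore area over cortex-compartment area, I_min is the smaller
principal second moment (with the per-pixel self term h^4/12), and the
section modulus divides by the largest perpendicular distance from the
I_min axis to the periosteal contour. Slices whose ring is broken (no
enclosed medullary cavity) are excluded with a warning; an entirely broken
stack is an error. The trabecular VOI is a caller-supplied slice range:
conventions like "n slices starting at a fixed offset from the growth
plate" are inputs, since automated growth-plate detection is out of scope —
and the printed slice bookkeeping of the source protocol is internally
inconsistent anyway (451 slices at 6 um is 2.706 mm against a stated
2.7 mm scan), so the package deliberately does not resolve it.

# Micro-finite-element failure load

Each segmented bone voxel inside the analysis cylinder (radius 1.25 mm in
the vertebral protocol; the printed "area = 49.3 mm^2" conflicts with that
radius by 10x and is ignored in favor of the radius) becomes an 8-node
hexahedral element. Elements are binned by TMD into 60 equal bins spanning
315.9-2787.3 mg HA/cm^3 (a ~41 mg HA/cm^3 increment; the printed "45-60
materials" corresponds to 60 at that increment) and receive the power-law
modulus E_t = 0.1127 x TMD_i^1.746 MPa, with TMD_i the median TMD of the
voxels in bin i and Poisson's ratio 0.3 everywhere. Only the largest
face-connected component spanning caudal to cranial is kept: floating
fragments would make the stiffness matrix singular.

High-friction compression fixes the caudal nodes in x, y, z and drives the
cranial nodes to 1% apparent strain with lateral constraint. The solver is
matrix-free Jacobi-preconditioned conjugate gradients over one reference
element stiffness (full 2 x 2 x 2 Gauss quadrature) scaled per element,
with a fixed summation order so residuals are reproducible; default
relative-residual tolerance 1e-6. The per-element equivalent strain is the
energy-equivalent form sqrt(2U/(E V)) — the convention of the
strain-percentile failure criterion literature; a von Mises alternative
was considered and rejected as the default because the energy form is what
the vendor chain reports. The failure load scales the reaction force so
that 2% of the bone volume exceeds an equivalent strain of 0.007; since
elements share one volume the volume quantile is the element-count
quantile, taken with linear interpolation (ties interpolate rather than
truncate — the source is silent, so the choice is documented here). By
linearity the failure load is invariant to the apparent strain used in the
solve, which the tests check to 1e-10.

The suite validates the solver against an independently written dense
assembly-and-solve oracle on every small model configuration (up to
5 x 5 x 5 voxels, mixed materials, random occupancy) at 1e-8 relative, the
confined-compression closed form E(1-nu)/((1+nu)(1-2nu)) A eps on a single
element to machine precision, global equilibrium to 1e-6 relative, and
monotonicity (stiffening with TMD, weakening with porosity). The
homogeneous-cylinder failure load moves by less than 2% between 12 um and
6 um voxels (it does *not* between 24 um and 12 um, where boundary
voxelization still dominates — problem sizes in the tests were chosen at
the finest resolution for which that contract holds at desk scale).

# Mechanical curve analysis

The analyzer applies a toe correction (back-extrapolating the stiffest
linear segment to zero force; raw origin behind a flag for audit), fits
stiffness as the best sliding-window regression by R^2 over the 20-80%
of-ultimate ascending limb (window 0.6 of the candidate segment — wide
enough to average 1% force noise to a ~2% stiffness error, short enough to
reject toe curvature), finds yield by the 0.9-secant criterion with
sub-sample interpolation, the ultimate from the raw record (smoothing would
clip sharp peaks; a moving average is used for detection only, and is
skipped entirely when a second-difference noise estimate says the record is
effectively noiseless), failure at the first post-ultimate sample below 10%
of ultimate, and work terms by trapezoid on the raw record (mJ = N mm).
The yield criterion itself lives in the protocol's cited prior
publications, not in the protocol text; the 0.9-secant rule is the declared
interpretation, is standard for rodent bending, and results carry the
criterion used. Vertebral compression strength uses a first-failure
convention (peak before the first drop exceeding 20% of the running
maximum) with the pure global maximum behind a flag.

Crack-initiation toughness treats the notched diaphysis as a thin-walled
pipe with a circumferential through-wall crack in bending:
K_c = F_b(theta/pi) sigma sqrt(pi r_m theta), with sigma = M r_o / I at the
notch section, M = F_ult S / 4, and F_b the Takahashi (2002) polynomial
1 + 6.8 x^1.5 - 13.6 x^2.5 + 20 x^3.5 tabulated in the module (validity
theta <= 110 degrees), the geometry factor the rodent-femur toughness
protocols use. Notch geometry is read from the mask stack: the notch plane
is the minimal-area slice, the wall radii come from equivalent-area fits on
the intact reference slice (the notch plane's own ring is open by
construction), and theta is half the angle of the longest missing arc of
the mid-wall circle, sampled at 0.25 degrees.

# CPMG relaxometry and bound water

The echo train is inverted to a T2 spectrum by non-negative least squares
with second-difference Tikhonov smoothing on a 128-point log grid spanning
1e-5 to 10 s, solved by an active-set method on the normal equations. The
regularization weight defaults to a discrepancy-principle choice against
the noise level estimated from the last decile of echoes, and is reported
with every spectrum; the bound-water window defaults to 50 us - 1 ms with
pore/free water above 1 ms, both configurable and always reported, since
the source protocol defers these details to a cited methods paper. The
reference microsphere (21.2 ul) is assumed co-acquired at the same gain
(relative gain configurable); calibration is linear by construction, and
bone volume comes from the Archimedes buoyancy formula.

A measured limitation: the "total spectral mass equals the extrapolated
t = 0 signal" property holds within ~1% at the protocol's acquisition SNR
(500 relative to the t = 0 amplitude, 10,000 echoes at 100 us spacing) but
degrades to several percent by SNR 100, because the non-negative inversion
lets the bound peak broaden toward short T2 where extrapolated mass per
unit observed signal grows like exp(t_1/T2). This is intrinsic
ill-posedness of the one-sided inverse Laplace transform — it persists as
the regularization weight goes to zero and under a reconstruction-support
floor — so the conservation test runs at SNR 500 with a documented sanity
band at SNR 100, and bound-water recovery contracts are stated as mean
error over seeds (the per-seed scatter at SNR 500 is +-5%, noise-variance
dominated).

# Statistical decision tree

Each outcome is first fit by a parametric two-way ANOVA of the 2 x 3
canagliflozin x glucose-group factorial with interaction, using Type III
sums of squares with sum-to-zero contrasts — the convention of the
commercial package such studies report, and the unbalanced-safe choice
(whether that package used Type II or III on mildly unbalanced groups is
unstated; Type III is the declared default). Residuals are screened by the
Anderson-Darling normality test and by Spearman correlation of absolute
residuals against fitted values; if either fails at alpha = 0.05 (fixed,
configurable), the aligned-rank-transform (ART) procedure replaces it: for
each effect, strip all other estimated effects via the unweighted cell-mean
decomposition, rank with mid-ranks, run the factorial ANOVA on ranks, and
read only that effect. The published ART correctness check — off-test
effects have F exactly zero on the *aligned, pre-ranking* response — is
computed with every fit; note that after ranking the off-test F is no
longer exactly zero even in the noiseless balanced case (ranking is
nonlinear), which is why the check is defined pre-ranking.

When the glucose-group or interaction effect is significant, the two
within-arm group families (3 pairwise comparisons each) are emitted; when
the canagliflozin or interaction effect is significant, the cross-arm
family (one contrast per glucose group) is emitted. Within each family,
pairwise pooled-SD t tests with Holm-Sidak step-down adjustment
(1 - (1 - p_(i))^(m-i+1), enforced monotone) are used when every involved
group passes Shapiro-Wilk and the family passes Brown-Forsythe
(median-centered Levene); otherwise Dunn's joint-rank z tests with mid-rank
tie correction and the same step-down family size. Groups of n < 3 force
the rank branch, since Shapiro-Wilk is undefined there. Mixed-effects
longitudinal modeling of the weekly body-mass/glucose curves is out of
scope; the factorial pipeline instead accepts per-animal summaries such as
the average of the last weeks of observation.

Calibration is verified by Monte Carlo: on 2,000 null Gaussian cohorts
(n = 10 per cell) both the parametric and ART branches hold per-effect
type-I error within [0.03, 0.07] at alpha = 0.05, diagnostics accept
well-behaved residuals in over 90% of replicates and detect proportional
heteroscedasticity in over 95%, and ART group-effect decisions agree with
the parametric decision on monotone-transformed additive data in over 90%
of replicates. The balanced-design F statistics are checked against
hand-computed sums of squares on an integer dataset.

# Problem sizes and numerical choices

Routine tests run phantoms at 12-24 um voxels (annulus, lattice, vertebral
body of ~70,000 elements), refine to 6 um only where a convergence claim
needs it, and use 2,000-replicate Monte Carlo for the statistics; the whole
suite runs in a few minutes on one core, and `scripts/acceptance.R`
recomputes the headline quantities in about two. Degenerate inputs are
contracts, not surprises: empty masks warn and flag, disconnected FE
models and all-broken cortical stacks error with named conditions, zero
prescribed strain returns zero reaction exactly, all-zero CPMG signals
return zero spectra, and constant or single-cell-empty cohorts error with
the offending cell named.
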