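---
title: "Canterakis-normalized 3D Zernike descriptors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canterakis-normalized 3D Zernike descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(zershape)
```

This vignette is the package's own account of the method it implements:
the model and its assumptions, the parameters that matter, the numerical
choices, and what the synthetic benchmarks do and do not demonstrate.

## From structure to density

A structure is reduced to representative atoms — one point per polymer
residue (C&alpha; for amino acids, the backbone phosphate for
nucleotides), weighted by the residue's average mass (monomer minus
water; unknown codes fall back to 110 Da, the average amino-acid residue
mass, so `residue_mass()` is total).  Ligands, waters and ions are
excluded; alternate locations keep the highest-occupancy conformer and
first occurrence otherwise, making parsing deterministic.  Assembly
operators are not expanded: the deposited coordinates (optionally a chain
subset) are used, and pre-expanded assembly files are handled naturally.

Each point contributes an isotropic Gaussian whose integral equals the
residue mass.  The per-residue width is derived from mean residue volumes
(Zamyatnin-style tables): sigma equals the radius of gyration of a
uniform sphere of that volume, `sigma = (3V/4pi)^(1/3) / sqrt(5)`,
between 1.1 and 1.8 Angstrom across the twenty amino acids.  This is a
coarse single-Gaussian stand-in for a residue's spherically averaged
shape; any published per-residue Gaussian fit could be substituted
without touching the rest of the pipeline.  Gaussians are truncated at
three sigma per axis (cubic truncation loses < 1 percent of the mass,
and the grid is padded so nothing is clipped).  The automatic grid-width
rule walks the ladder `0.25 * 2^k` Angstrom (k = 0..6) and takes the
finest width that keeps the mean grid dimension between 50 and 200
voxels; because the admissible interval spans a factor of four and the
ladder steps by two, such a width exists whenever the interval meets
[0.25, 16].  We read the 50–200 range as a voxel count: as a physical
length it would contradict the stated width range for typical proteins.

The density is scaled into the unit ball about its mass-weighted centroid
with scale `1/(1.8 Rg)`.  The factor 1.8 leaves elongated shapes with a
small mass fraction outside the ball; that tail is ignored by the moment
quadrature, which is part of the method's definition rather than an
error.

## Moments, invariants, normalization

Zernike moments are voxel-centre sums of the density against the
orthonormal basis `Z_nlm = R_nl(r) Y_lm(theta, phi)` up to order
N = 20 (946 stored coefficients with m >= 0; negative m follow from the
conjugation symmetry of real densities).  The radial polynomials are
Jacobi polynomials in `2r^2 - 1`, normalized so that
`integral R_nl R_n'l r^2 dr = delta`; the spherical harmonics are
orthonormal with Condon–Shortley phase and an additional `(-i)^m`
azimuthal gauge.  That gauge is deliberate: it is the unique choice (up
to a global flip) under which the Cayley–Klein transformation law, the
printed rotation matrix `R(a, b)` and conjugation symmetry hold
simultaneously.  Under it, `rotate_moments(M, rot)` equals the moments of
the substituted density `f(R x)`, i.e. of the point cloud moved by
`t(R) = ck_point_matrix(rot)`.  The test suite pins this convention with
an exact oracle: moments of weighted point sets (delta densities) can be
evaluated without any grid, so moment-space rotation must agree with
real-space rotation to machine precision.

The scaling constants `c_lm` that turn moments into their "modified"
form are implemented as `(2l+1)/l! * sqrt((l+m)!(l-m)!)`.  Only the
m-dependence matters — the l-only prefactor cancels both in the
normalization polynomials and in the round trip — and the square root on
the factorials is required for consistency with real-space rotation,
which the same oracle verifies.

A Canterakis normalization of order n drives the modified moment
`(n, l, m) = (n, 2, 2)` (even n) or `(n, 3, 3)` (odd n) to zero.
Substituting `t = a / conj(b)` turns the constraint into a degree-2l
complex polynomial whose coefficients are, up to alternating signs, the
full-m moment vector; roots come from the companion matrix (`polyroot`),
with near-zero leading coefficients deflated.  The residual in-plane
angle is fixed by requiring `Im(rotated Omega_311) = 0`, a real quadratic
in `s = Im(b)/Re(b)` whose coefficients we obtain by exact interpolation
at s = -1, 0, 1 rather than from a hand-expanded formula — the same
machinery therefore serves every order and constraint.  The gauge
`Re(b) > 0` is built into the parameter recovery.  Generic moments yield
8 solutions for the (2,2) system (4 roots x 2); all are verified by
back-substitution, and each returned rotation drives the constrained
moment below 1e-8 of the moment scale.

Descriptors average complex magnitudes over all solutions, which removes
both the in-plane degree of freedom (magnitudes are invariant to
z-rotations in the normalized frame) and the solution multiplicity.  We
average magnitudes of the rotated values (not values before taking
magnitudes); the opposite order would destroy the invariance.  When a
moment set carries no orientation signal at all for a given constraint
(all polynomial coefficients at noise level, e.g. perfect spherical
symmetry), the solver flags the normalization as degenerate and the
descriptor falls back to raw magnitudes.  For *nearly* symmetric shapes
(Cn rings) the constraint moments are noise-dominated and the recovered
axis can tilt by a noise-driven amount; the averaged magnitudes then
fluctuate more than for generic shapes.  This is an intrinsic property
of the normalization, visible in the benchmark as a weaker CN backend on
highly symmetric fixtures, and is the reason the composite descriptor
also carries GEO.

## Distance and weight fitting

The descriptor distance applies squared weights to relativized GEO
differences and linear weights to absolute CN differences; it is
symmetric and non-negative but not a metric (no triangle inequality is
claimed or tested).  Weights are fitted as a logistic regression of the
pair label on exactly these per-component terms, with coefficients
constrained non-positive so that the fitted linear score *is* the
negated distance; weights are the negated coefficients, and `wg` is
recovered by a square root.  Regularization is L1.  We first implemented
the L2-with-projection variant; it left essentially all 3801
coefficients non-zero, while the L1 path reproduces the sparse behaviour
this method is known for (a minority of components carrying all the
weight) and gave better held-out MCC, so the package ships L1 as its
design choice.  The penalty strength is selected by 10-fold
cross-validation grouped at the class level (a class never straddles
folds; a pair inherits the fold of its first member's class), maximizing
the Matthews correlation coefficient of the held-out hard
classifications.  Fold assignment is a seeded function of the sorted
class labels, so permuting the input pairs cannot change the result.

## Alignment

The alignment descriptor stores complete moments to order 6 plus the
centre of mass (lost by unit-ball scaling).  Candidate normalizations of
orders 2–5 are enumerated for both structures — all polynomial solutions,
the "testing all possibilities" strategy — and the pair of rotations of a
common order minimizing the relative moment distance in standard
position is selected; ties break toward the lowest order and first
solution.  Order-2 normalization is principal-axis alignment; higher
orders lock finer detail.  For more than two structures the reference
structure's candidate is chosen to minimize the summed distance of every
other structure's best candidate, keeping the cost linear in the number
of structures.  Recovered rotations are defined only modulo the shape's
symmetry group; for symmetric inputs the reported transform is one valid
representative.  RMSD over representative atoms is computed purely as a
quality metric — the method itself never uses correspondences.  When
every candidate normalization is degenerate, superposition falls back to
centre-of-mass translation and is flagged.

## Synthetic benchmark: what it emulates and what it does not

The fixtures module generates five base-shape families (chiral helix
bundles, exact-Cn rings, dumbbells, slabs, random ellipsoidal blobs) with
seeded, bitwise-reproducible parameters, and populates each class with
conformers produced by a smooth displacement field: three random
long-wavelength sinusoidal modes normalized to a requested RMS amplitude.
This emulates the statistical design of an assemblies benchmark — classes
of genuinely distinct shapes, each with a handful of collective-motion
conformers — without an elastic-network model: the displacement field
preserves what matters statistically (smooth, low-frequency, per-class
deformations) but has no physical force constants.  Class bases are
rejected unless they clear a documented GEO-distance floor (0.5) against
every accepted class, the analog of enforcing a low density-correlation
ceiling between benchmark entries.

Default study conditions: the test benchmark uses 20 classes x 5
conformers at 0.5 Angstrom RMS amplitude (a small, clearly within-class
deformation for shapes of 12–24 Angstrom radius); weights are fitted on
an independent benchmark of 10 classes x 4 members at 1.5 Angstrom with a
different seed, mirroring the separation of training and evaluation
structures.  Descriptor grids use an explicit 1.5 Angstrom width in the
benchmarks (problem sizes chosen so the full suite runs in minutes on one
CPU); the 64-voxel-scale rotation oracle uses a width derived from the
shape's extent.  Passing these tests shows the *machinery* is correct
and that the composite descriptor dominates its components on data with
this statistical structure; it does not show anything about real fold
statistics, experimental maps, or the absolute AUC values one would
obtain on curated structure databases.

Because the fixtures classes differ partly in size, GEO alone separates
them almost perfectly, and the size-blind CN descriptor adds little on
*these* conditions — with uniform weights it can even cost a pair
ordering or two.  The fitted weights resolve this exactly as the full
method prescribes: components that do not help the class signal are
zeroed, so the composite is never worse than its best component.  This
mirrors the known behaviour on real assembly benchmarks, where the
geometric features alone already achieve near-perfect ROC AUC and the
weighted composite matches them while adding precision.

## Numerical notes and limitations

* Voxels participate in the quadrature iff their centre lies inside the
  unit sphere; moment accuracy and the rotation-oracle error scale with
  grid width (about 0.6 percent L2 at ~60^3 for typical fixtures).
* Moment rotation is exact algebra (unitary per (n, l) block); per-(n,l)
  norms are preserved to machine precision, which is precisely why 3DZD
  carries no orientation information and the normalization does.
* Normalization tolerances: coefficient deflation and degeneracy use a
  1e-12 relative floor; solution residuals are checked against 1e-8 of
  the constrained vector's scale.
* The quadratic for the in-plane angle can lack real roots for
  symmetric-degenerate inputs; the solver then keeps s = 0, keeping the
  solution count stable.
* Elongated structures keep a small mass fraction outside the unit ball
  by construction (scale 1/(1.8 Rg)); descriptors remain comparable
  because every structure is treated identically.
* No local or partial matching: the representation is global by design.
  Experimental-map preprocessing (contour selection, noise filtering) is
  out of scope; volumes enter the pipeline only via the rasterizer.
* CCP4/MRC volume import/export is not provided; moments are computed
  from the internal volume container, which external code can populate
  directly (`new_volume`).
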