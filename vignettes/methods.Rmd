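---
title: "Methods: pre-processing grids, radiomics features, and test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-processing grids, radiomics features, and test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Radiomics turns a delineated lesion in a 3D scan into a vector of
quantitative descriptors — intensity statistics, texture-matrix summaries,
and shape measures. Before any of these can serve as imaging biomarkers they
must be *reproducible*: a patient scanned twice in quick succession, with no
intervening change, should yield nearly the same feature values. For
T2-weighted prostate MRI this is particularly delicate because the
intensities are in arbitrary units, so the pre-processing pipeline
(normalization, outlier handling, and gray-level discretization) can move
features more than biology does.

`radrepro` implements the full apparatus for quantifying this: a
48-setting pre-processing grid, a self-contained 107-feature extraction
engine, ICC(2,1) reliability scoring, selection of the best setting, and
nonparametric comparisons of reproducibility across clinical subgroups —
plus a synthetic paired-cohort generator with *known* true reliability so
that every stage can be validated without patient data.

## The pre-processing grid

Three parameters are crossed into 2 x 4 x 2 x 3 = 48 settings
(`enumerate_settings()`):

* **Gray-level discretization**: fixed bin number (FBN; 16, 32, 64, 128
  bins over the in-mask intensity range) or fixed bin size (FBS; absolute
  bin widths 5, 10, 20, 40 intensity units, edges anchored at multiples of
  the width). FBN is invariant under positive affine intensity maps — the
  floor formula cancels gain and offset exactly — while FBS is deliberately
  scale-sensitive. This algebraic fact is the mechanism by which relative
  discretization absorbs arbitrary-unit scanner drift, and the package
  asserts it bit-exactly in its tests.
* **Signal-intensity normalization**: either none (NAR) or a dual-reference
  affine map (AR) that sends the mean intensity of a muscle reference
  region to 0 and of a fat reference region to 1000. The original
  dual-reference method detects those tissues automatically; here reference
  masks are supplied explicitly, which keeps the contract (a monotone
  two-point affine anchor) while avoiding a detection algorithm that is out
  of scope. The anchor values are configurable because the reference
  method's exact targets are not published; 0/1000 spans a plausible
  arbitrary-unit range.
* **Intensity outlier filtering**: none (NoF), clip in-mask values into
  [mu - 3 sigma, mu + 3 sigma] (IN), or remove voxels outside that range
  from the mask (OUT). mu and sigma are computed once from the input, not
  iterated. Sigma uses the sample (n - 1) denominator; sources do not
  specify it, so it is exposed as an argument.

Pipeline order is normalization, then outlier filtering, then
discretization — the standard processing order for radiomics pipelines, and
the only order in which the outlier bounds reflect the intensities actually
discretized. Because the normalization is affine and the outlier rule is
affine-equivariant, AR and NAR remove identical voxel sets under OUT; the
final mask therefore depends only on the outlier mode, which the extraction
engine exploits by caching shape features.

## The feature engine

107 features in 7 groups (18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM, 16
GLSZM, 5 NGTDM, 14 shape), with the conventions of the widely used
extraction tooling the counts come from: all neighborhoods at Chebyshev
distance 1; GLCM symmetrized and normalized per direction; GLCM and GLRLM
features computed per direction and averaged over the 13 unique 3D offsets;
GLSZM zones 26-connected; GLDM dependence = 1 + the number of neighbors
with identical gray level (tolerance 0); matrices indexed over the gray
levels actually present with formulas using the level *values*. First-order
statistics use the continuous post-filter intensities except Entropy and
Uniformity, which use the discretized histogram; population (N) moments;
type-7 percentiles; Kurtosis is the raw fourth standardized moment (normal
gives 3).

Degenerate inputs are mapped to documented constants: a single-gray-level
ROI gives entropies 0, Imc1 = Imc2 = 0, Correlation = MCC = 1; NGTDM
Coarseness with a vanishing denominator returns 1e6, Busyness and Strength
return 0; single-voxel masks give zero axis lengths and Elongation =
Flatness = 0.

**Validation.** The intended cross-validation oracle (the reference
radiomics engine) cannot be installed in this build environment, so the
test suite instead carries a second, fully independent implementation:
naive enumeration loops coded directly from the definitions, for every
matrix family and every formula. The vectorized engine must agree with it
to 1e-6 relative on dozens of random ROIs, and conservation laws (GLCM
normalization, run/zone voxel-count conservation, dependence row sums) are
asserted on every test ROI. This is weaker than agreement with an external
engine — a misreading of a published definition could in principle be
shared by both routes — but the two implementations share no code and the
worked micro-examples (hand-enumerated GLCMs, hand-summed first-order
values) pin the conventions independently.

**Shape and the mesh.** The surface mesh is a marching-tetrahedra
triangulation of the 0.5 iso-surface of the zero-padded binary mask in
physical coordinates: each lattice cube is split into six tetrahedra and
crossings are at edge midpoints. The classic 256-case marching-cubes
triangle table was deliberately avoided (it cannot be reproduced reliably
from memory, and copying it from an installed package is not acceptable);
the tetrahedral decomposition needs only three local cases and yields a
closed, consistently oriented surface, verified in the tests by checking
that every directed edge appears exactly once with its reverse. MeshVolume
is then the exact divergence-theorem volume of the enclosed polyhedron and
converges to the analytic volume for digital balls. SurfaceArea, however,
inherits the faceting of any midpoint triangulation of *binary* data: for
spheres it overestimates the analytic area by a roughly constant factor
(about 4/pi for marching tetrahedra; classic marching cubes on binary masks
overestimates by roughly 9%). Sphericity therefore increases with radius
but plateaus below 1 rather than converging to it — a property of every
binary-mask mesher, asserted as such in the tests. Because the bias is a
deterministic function of the mask, it is identical across the two scans of
a test-retest pair and cancels in reliability analyses; absolute surface
areas should not be compared against tools using a different mesher.

## Reliability scoring and setting selection

`icc_2_1()` computes the two-way random-effects, absolute-agreement,
single-measurement intra-class correlation from the crossed ANOVA mean
squares: ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)) with k =
2 scans. Point estimates only (no confidence intervals, matching the
analysis this package reproduces); negative estimates are retained;
all-identical tables (zero denominator) are reported as 1 with a
`degenerate` flag and excluded from good-feature counts. A feature is
"good" if ICC > 0.75, strictly. The winning setting maximizes the
good-feature count; ties are broken by the lowest binning value. The
published tie-break is undefined when an FBN bin *number* ties an FBS bin
*width* numerically or when equal binning values remain; the residual case
is resolved by lowest setting index with a warning rather than by guessing
intent.

## Group comparisons

Clinical subgroups use the published cut-offs: PSAD low (<= 0.15 ng/mL^2)
vs high; prostate volume small (< 40 mL) vs enlarged; PI-RADS 3/4/5; ISUP
< 1 (benign, coded 0), 1, > 1. Two-category variables are compared with the
two-tailed Mann-Whitney U test (exact enumeration below combined n = 12
without ties, otherwise normal approximation with mid-ranks, tie and
continuity corrections); three-category variables with Kruskal-Wallis
(tie-corrected H, chi-squared reference). Multiplicity is controlled with
Benjamini-Hochberg step-up adjustment. "Performed separately followed by
correction" is read as one family per clinical variable for the
feature-value tests (matching the per-column significance layout of the
published table) and one family across variables for the ICC-distribution
tests; the alternative single global family is available via the `family`
argument. Categories with fewer than 3 lesions make the within-category
ICC incomputable; the variable is flagged and excluded from the family
rather than imputed.

## The synthetic cohort: what it emulates, and what a green test means

No patient data are distributable, so `generate_cohort()` builds a stand-in
cohort whose *structure* matches the study it emulates: 50 patients, 74
lesions (one index lesion per patient, extras spread at most 3 per
patient), PI-RADS sampled 18/30/26 over 3/4/5, ISUP 11/8/15/8/6/2 over
<1 and 1..5, PSAD and prostate volume lognormal with mean +/- SD 0.34 +/-
0.30 ng/mL^2 and 46.94 +/- 19.49 mL, voxels 0.5 x 0.5 x 3 mm.

Each lesion's in-mask signal is

    gain_s * (base + a_l * T_l + e_ls * U_ls + noise) + offset_s

with T_l a smoothed Gaussian random field shared by both scans, U_ls an
independent field per scan, a_l ~ N(0, var_shared), e_ls ~ N(0,
var_independent), and gain/offset drift on scan 2 drawn from [0.8, 1.25]
and [-50, 50] arbitrary units — drift being exactly the nuisance FBN and
normalization must absorb. The ratio var_shared / (var_shared +
var_independent) is a known reliability anchor (`expected_reliability()`),
and the tabular generator `simulate_feature_table()` gives the exact
two-way-random model for estimator validation. Masks are mid-grid
ellipsoids with per-scan boundary-voxel jitter (one-voxel flips), emulating
independent delineation of the two scans; fat and muscle reference boxes
sit in grid corners.

Defaults chosen where no source states a value, fixed once: var_shared =
var_independent = 1 (true reliability 0.5, the same order as the mean
reproducibility the emulated study observed); lesion semi-axes 4-12 mm
(lesion size distributions are unpublished; this spans small to large
index lesions and is exposed in the config, not asserted anywhere); base
level 400, texture amplitude 80 and noise SD 10 arbitrary units (texture
dominates noise, as in T2WI of visible lesions); smoothing sigmas (2, 2,
0.5) voxels, giving in-plane correlation lengths of about 1 mm so that
co-occurrence structure is nontrivial at every binning. Clinical variables
are drawn independently of the texture by default — the null that the
emulated analysis could not reject — so subgroup comparisons are calibrated
rather than powered; planted-effect configurations are built in the tests
from the tabular generator instead.

What the simulator does *not* model: prostate anatomy, MR physics (bias
fields, Rician noise, coil profiles), inter-scan registration error beyond
mask jitter, or any coupling between lesion aggressiveness and texture. A
green end-to-end test therefore establishes that the machinery is correct
and calibrated, not that any clinical conclusion transfers.

## Numerical choices

* Entropies in bits, summed over positive entries only.
* Percentiles by linear interpolation (type 7).
* ICC degenerate threshold: denominator below machine epsilon relative to
  MSR.
* FBS edges are half-open [edge, edge + width), so a value on an edge joins
  the bin above; FBN clamps the maximum into the top bin.
* All randomness runs through R's Mersenne-Twister with inversion sampling,
  seeded explicitly; identical configurations are bit-reproducible.
* Full-size runs (74 lesions x 2 scans x 48 settings at default lesion
  sizes) take on the order of an hour on one CPU in pure R; tests and the
  acceptance script use a reduced cohort (20 lesions, small ROIs, full
  grid) that completes in about two minutes.

## Known limitations

* SurfaceArea (and hence Sphericity and SurfaceVolumeRatio) carries the
  binary-mesh faceting bias discussed above.
* The exact-vs-approximate switch in the Mann-Whitney test is a documented
  convention; near the switch boundary p-values move by up to ~0.02.
* The NIfTI reader/writer covers the single-file little-endian subset this
  pipeline writes; it is not a general NIfTI implementation.
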