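---
title: "Projecting task fMRI onto white matter circuits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting task fMRI onto white matter circuits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnkit)
```

## The problem

Classical task-fMRI analysis treats every voxel independently and recovers
grey-matter activation maps; the white matter, whose BOLD signal is weak and
of debated interpretability, stays invisible. Yet a task that engages two
distant cortical regions necessarily engages the fibre pathway linking them.
`fnkit` implements a circuit-level analysis: grey-matter BOLD is *projected*
onto the white matter through anatomical connectivity priors derived from
streamline tractography, and the projected 4D volume is then analysed with
the same statistical machinery as ordinary fMRI. Activations in the
projected maps are statements about pathways — they are a re-weighting of
grey-matter signal, not direct white-matter BOLD measurements.

## Anatomical connectivity priors

For a seed $m$ (a voxel, or a parcellation region in the "simplified"
region-wise variant) and a subject's whole-brain tractogram, every
streamline that intersects the seed is rasterised onto the analysis grid and
the union of the visited voxels is binarised. Averaging these binary
visitation maps over $n$ subjects gives the prior $P_m(v) \in \{0, 1/n,
\dots, 1\}$: the population frequency with which a streamline links $m$ to
voxel $v$. The package applies no threshold to these probabilities, and
seeds crossed by no streamline keep an explicit all-zero entry, so that
downstream projection can report uncovered voxels instead of silently
dropping them.

Rasterisation follows the NIfTI geometry convention throughout: voxel
indices are 0-based, the world position of the *center* of voxel $(i,j,k)$
is $A\,(i,j,k,1)^T$ for the grid affine $A$, and the voxel containing a
world point is the rounded continuous voxel coordinate. The default backend
resamples every polyline segment at a step of $\min(\text{voxel size})/4$
and collects containing voxels — the convention of common streamline-density
implementations. An analytic boundary-crossing traversal
(`method = "exact"`) is available as a reference backend; the two differ
only on voxels a polyline grazes for less than the resampling step, which
the test suite checks explicitly.

Priors are held column-wise in one sparse matrix (voxels × seeds), which is
simultaneously the persistence layout and the operand of the projection.
The on-disk archive is a single version-tagged RDS container storing mode,
shape, affine, keys and the sparse triplets; the logical layout
(grid attributes plus one sparse record per seed) mirrors keyed
scientific-archive formats, and `read_priors()`/`write_priors()` round-trip
it exactly. No container format is canonical for such priors; a single
seekable archive was chosen over hundreds of thousands of loose map files
for filesystem sanity.

## The projection

For the analysis mask $M$ (the grey-matter/"good voxels" mask) and input
BOLD $F$, the projected volume is

$$\mathrm{proj}(v,t) \;=\;
\frac{\sum_{m \in M} P_m(v)\, F(m,t)}{\sum_{m \in M} P_m(v)},$$

a convex combination of the contributing time-series: every covered output
value lies between the min and max of the inputs that reach it, so the
projected volume lives on the same scale as the BOLD signal. Region-wise
projection is identical with $m$ ranging over parcels and $F(m,t)$ replaced
by the parcel-mean time-series; with singleton regions it reduces exactly
to the voxel-wise transform (tested).

Implementation decisions, all asserted by tests:

* **Zero-denominator voxels** output 0 at all time points and are returned
  as an explicit `uncovered` mask, rather than NaN — this keeps any
  downstream GLM finite while preserving the information.
* **Raw averaged probabilities** are used as weights; individual prior maps
  are not re-normalised before projection (the ratio already normalises per
  output voxel, and per-map normalisation would change the relative weight
  of sparsely and densely connected seeds).
* **Linearity, permutation invariance and chunked execution**: the
  transform is linear in $F$, independent of seed ordering, and the
  time-chunked path is bit-identical to the all-in-memory path (it exists
  only to bound peak memory).
* **No smoothing is ever applied to projected volumes.** The projection
  already pools signal — along circuits rather than across neighbours — so
  the usual SNR motivation for Gaussian smoothing does not apply; the
  classical comparison arm is smoothed (default FWHM 4 mm).

## Activation statistics

The statistical layer deliberately implements the *shape* of the standard
two-level workflow with transparent numerics rather than replicating any
specific neuroimaging suite:

* **Design**: a boxcar at 0.1 s micro-time resolution convolved with the
  canonical double-gamma HRF (response peak 6 s, undershoot 16 s,
  peak:undershoot 6 — the conventional defaults), sampled at frame times,
  scaled to unit peak (so betas are in units of peak signal change) and
  mean-centred alongside an intercept. A zero-variance task regressor is
  flagged collinear and rejected at fit time. Note that a block covering
  the whole run is *not* degenerate: the HRF ramp-in leaves usable variance.
* **First level**: per-voxel ordinary least squares; $t =$ effect / SE with
  dof $T - K$; optional per-voxel Cochrane–Orcutt AR(1) prewhitening for
  autocorrelated noise (off by default — the phantom's noise is white, and
  a projected volume is a fixed linear combination of signals for which the
  i.i.d. assumption held).
* **Group level**: a one-sample t on first-level effects (dof $n-1$).
* **z transform**: the exact Student tail computed in log space and mapped
  through the normal quantile, symmetric by construction and capped at
  $\pm 38$, the double-precision limit. Standard errors and group variances
  are floored at $10^{-12}$, so exact fits yield large finite statistics.
  At low dof the heavy Student tail means the cap is never reached (a
  zero-variance group of 5 gives $z \approx 10.4$, not 38); the cap binds
  at first-level dof.
* **Smoothing** (classical arm only): separable per-axis Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ converted to voxels per axis,
  kernels renormalised at boundaries so constants are preserved exactly.

Multiple-comparison correction is out of scope; comparisons in the phantom
study are rank- and effect-based rather than threshold-based.

## Map comparison

`pearson_spatial()` is the plain Pearson correlation over a caller-supplied
brain mask (defaulting to the union of nonzero voxels — "excluding voxels
outside the brain" is a mask decision, not a statistic decision).
Reproducibility tables correlate run-1 and run-2 group z-maps per task and
summarise mean ± sd across tasks; z-maps are correlated raw, not
thresholded. `crosscorr_matrix()` correlates two sets of component maps
with the negative parts zeroed by default (the usual convention when
matching signed decomposition maps) and reports the per-row argmax
assignment. The decompositions themselves (e.g. ICA) are deliberately not
reimplemented; any externally produced maps can be compared.

## The phantom and what it does (not) show

`make_phantom()` builds a 20×20×20 grid of 2 mm voxels: two 27-voxel
grey-matter regions A and B on the mid-axial line joined by an 8-voxel
straight tract, a control region C attached to a distractor path, and a
white-matter slab containing the tract. Positions are fixed fractions of
the grid extent, so counts scale with the configured shape.
`simulate_streamlines()` draws 20 bundle polylines per subject from voxels
of A through the tract spine to voxels of B, plus 10 distractors (half
through C, half free-floating), each point jittered with isotropic Gaussian
noise of sd 1 mm (half a voxel — a realistic bundle spread at this
resolution); with zero jitter the bundle rasterises exactly onto the spine,
which makes subject-averaged priors exact rational fractions and is how the
priors arithmetic is verified. `simulate_bold()` adds to a baseline of 100
the unit-peak task regressor scaled by each region's amplitude (so
amplitude 1 is a 1% signal change) and i.i.d. Gaussian noise (sd 1 by
default; an AR(1) option exists to exercise prewhitening). Two runs per
subject differ only in their noise stream, emulating a test–retest
acquisition pair.

The reference study conditions — 10 subjects, 200 frames at TR 1 s, 15 s
blocks every 40 s, both endpoints at 1% amplitude, 1% noise — are what
`run_phantom_experiment()` executes end to end: priors from the simulated
tractograms, projection of each run, first-level OLS per subject
(functionnectome arm unsmoothed, classical arm smoothed at 4 mm), and group
z-maps. The test suite checks, under these conditions, that the tract's
mean group z in the projected arm exceeds the 95th percentile of non-tract
white matter while the classical arm shows no such effect; that silencing
one endpoint lowers the median tract z (the coincidence penalty: a circuit
is only as active as both of its ends); and that across 10 seeded
repetitions the projected arm's run-to-run spatial correlation beats the
smoothed classical arm's in at least 9. These problem sizes keep the whole
suite within a few minutes on a single core while leaving the group-level
statistics well away from small-sample degeneracy.

What the phantom does *not* emulate: hemodynamic variability across regions
and subjects, physiological and motion noise, geometric distortion,
registration error, partial-volume effects, crossing or fanning fibre
configurations, and tractography false positives/negatives. Passing the
phantom checks therefore validates the *arithmetic and the statistical
logic* of the pipeline — that the projection equation, priors averaging and
two-level GLM do what they claim under known ground truth — not the
anatomical accuracy of any real-data result.

## Degenerate inputs and tie-breaks

* Streamlines entirely outside the grid rasterise to the empty set; a
  degenerate polyline (all points identical) maps to its single containing
  voxel.
* A seed crossed by no streamline yields an all-zero prior, kept in the
  store; projecting with it simply contributes nothing.
* An empty analysis mask, a mask voxel without a priors entry (reported by
  key), grid mismatches (affines compared at 1e-4 mm absolute tolerance),
  unpaired reproducibility inputs, and correlation over fewer than 3 voxels
  or against a constant map are all hard errors.
* Empty tractogram files read as empty sets with a warning, so a subject
  with no reconstructed streamlines is visible but not fatal.

## Limitations

Region-wise priors trade spatial specificity for speed exactly as the
voxel-wise/simplified distinction intends; the package does not resample
between grids (inputs must share one grid), does not handle surface-based
data, and its GLM is a deliberately simplified stand-in for full
neuroimaging pipelines — adequate for the phantom's white-noise conditions
and for method-level comparisons, not a drop-in replacement for
prewhitened, mixed-effects real-data analysis.
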