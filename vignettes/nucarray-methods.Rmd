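---
title: "Measuring and simulating nucleosome array geometry with nucarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and simulating nucleosome array geometry with nucarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

A nucleosome core particle (NCP) wraps ~147 bp of DNA in ~1.7 left-handed
superhelical turns around a histone octamer; in an array, NCPs alternate
with linker DNA. Per-particle structural models of such arrays — a 3D
helical-center coordinate for every base pair plus the positions of the
octamers — make it possible to quantify, molecule by molecule, how far each
NCP is unwrapped and how its two DNA arms are oriented, and then to ask how
those distributions change with salt or linker histone H1, and what they
imply for the morphology and density of long chromatin fibers.

`nucarray` implements that pipeline end to end on a package-defined model
format: wrapped-interval detection, NCP frame fitting, arm-angle
measurement, footprints, inter-NCP distances and plane dihedrals,
distribution statistics (mixtures, kernel densities, two-state Boltzmann
gaps, a random-plane dihedral null), RMSD-based conformational
classification, a coarse-grained 100-NCP fiber simulator with
worm-like-chain analysis, condensate density estimation, and a synthetic
array generator that doubles as the package's ground-truth test bed.

## The geometric model

All geometry is referred to one idealised wrapped path: a left-handed
superhelix of radius 41.8 Å and pitch 25.0 Å making 1.7 turns over 147 bp
(~4.163° of superhelical phase per bp). Each NCP carries an orthonormal
frame: **Z** along the superhelical axis pointing in the entry-to-exit
direction of advance, **Y** from the center toward the dyad base pair, and
**X = Y × Z**. "Entry" is always the side facing the longer (200-bp)
designed arm; templates follow the segment arithmetic entry + n·147 +
(n−1)·linker + exit (447, 634, 821, 1008 bp for one to four NCPs with the
default 200/40/100-bp segments).

Per-NCP quantities:

* `delta_entry_bp`, `delta_exit_bp` — signed deviations of the detected
  wrapped interval from the designed repeat; negative means peeled
  ("breathing") DNA. `wrap_length_bp = 147 + delta_entry + delta_exit`.
* `theta` — unsigned 3D angle between the two 20-bp arm vectors (both
  pointing away from the NCP).
* `theta_par`, `theta_perp` — signed projections of that angle onto the
  discoidal (XY) and perpendicular (YZ) planes; `theta_par < 0` defines the
  closed-arm state (0 counts as open).
* `alpha` — signed in-plane angle from the local wrapped-path tangent at
  the arm origin to the arm's XY projection, positive rotating radially
  outward. The same convention on both sides makes entry and exit angles
  poolable.
* `beta` — `arcsin(arm · Z)`, the out-of-plane bending angle.

Sign conventions the source definitions leave open were fixed once, as
above, and are used identically by the generator and the measurement code.

## Wrapped-interval detection

Detection asks, per designed repeat: which trace base pairs lie on the
ideal wrapped path? The positioning sequence fixes the registration (bp
`j` of the trace corresponds to path position `j − repeat_start`), so
alignment is a robust fixed-correspondence superposition: a Cauchy-weighted
iteratively reweighted Kabsch fit, then hard trimming down to the residual
scale. Base pairs within 8 Å of the aligned path form the contact run;
interior gaps of ≤ 2 bp are always bridged, and longer gaps are bridged
when every gap bp stays within 1.5× the contact radius, so that noise
excursions just past the criterion cannot split a wrapped run.

The raw 8 Å rule systematically overshoots: a straight arm leaving the
wrap stays within 8 Å of the continuing helix for its first few base
pairs (for an arm leaving near the tangent, up to ~8 bp). Each boundary is
therefore refined by a changepoint criterion that scores every candidate
against two locally fitted models — the ideal helix re-superposed on 20 bp
inward, a straight line fitted to up to 20 bp outward (never crossing into
a neighbouring repeat) — choosing the boundary with the smallest total
residual. Because the origin base pair lies on both the wrapped path and
the arm line, exact ties are broken toward the maximal wrap; candidates
may move the coarse boundary 10 bp inward but only 2 bp outward,
reflecting the one-sided nature of the 8 Å overshoot. On noise-free
models this recovers the generated boundaries exactly.

**Known limitation (identifiability).** With 2 Å coordinate noise, an arm
that leaves the wrap near the local tangent (`alpha ≈ 0`, `beta ≈ 0`) is
geometrically indistinguishable from 1–3 bp of continuing wrapped path; no
boundary criterion can resolve it. Boundaries of such arms are
over-detected by ~1–2 bp on average, and their measured `alpha` is
correspondingly biased a few degrees positive. Steep arms and all
zero-noise models are unbiased. This propagates into the minor
(near-tangential) component of the wrapping-angle mixtures: its recovered
mean can sit several degrees above the generating value even at the
default study conditions, which is why the parameter-recovery check can
fail for that component while every other parameter passes.

## Frame fitting and angle measurement

`fit_ncp_frame()` superposes the ideal superhelix (dyad at the geometric
midpoint of the run) on the wrapped points by Kabsch with fixed
correspondence. Using the full helix structure — phase and rise, not just
the radial spread of a cylinder — makes the axis much less noise-sensitive,
and the construction is exactly equivariant under rigid motion. With
asymmetric unwrapping the geometric midpoint differs from the
sequence-defined dyad by half the delta difference; the difference rotates
the frame about Z and cancels out of every angle defined here.

For `alpha`, the reference tangent is evaluated at a continuous contact
point: the closest approach of the measured arm line to the fitted
superhelix (searched within ±2 bp of the detected boundary), with the
helix phase and axial intercept estimated by regression over all wrapped
base pairs (known twist and rise per bp, free intercepts). This decouples
`alpha` from the ±1 bp discreteness of the boundary, which would otherwise
rotate the tangent by ~4.2° per bp. Arm directions come from the principal
axis of the 20-bp segment, offset 2 bp from the boundary so small inward
boundary errors cannot mix wrapped base pairs into the arm (for a straight
arm the direction is unchanged).

## Distribution statistics

Angle samples are treated as linear (not circular) variables — their
observed ranges are well inside ±180° — and fitted with one- or
two-component Gaussian mixtures (maximum likelihood via EM with
model-based hierarchical initialisation; BIC selects the component count
when requested). The two mixture weights of a bimodal wrapping-angle
distribution are the two state populations, converted to an energy gap by
`dU = −ln(p_i/p_j)` (in kT). Note that gaps recomputed from *rounded*
populations differ by a few percent from values computed from unrounded
ones — e.g. populations printed as 38%/62% give −ln(38/62) = 0.490.
Dihedral-angle distributions are compared with the random-plane null
(density `sin(phi)` on [0°, 90°], CDF `1 − cos(phi)`) by a one-sample
Kolmogorov–Smirnov statistic with asymptotic p-values.

## The synthetic generator

`generate_array()` builds arrays from the same primitives the measurement
assumes: ideal superhelical wraps trimmed by sampled integer deltas
(Gaussian, rounded, clamped to [−40, +10]), straight arms and linkers at
3.4 Å/bp in directions sampled from per-side `(alpha, beta)`
distributions, a 70° left-handed twist per linker, a random global rigid
motion, and coordinate noise. Presets carry the per-condition statistics
(mono 5 mM; di/tri/tetra 5 mM; tetra 50 mM; tetra +H1); dispersions only
reported for the mononucleosome condition are reused as defaults elsewhere
and flagged `partially_specified`.

The noise model is smoothly correlated isotropic Gaussian displacement
(moving average over 15 bp, marginal sd `noise_sd`, default 2 Å) with
minimal longitudinal corrections keeping consecutive spacings in the
[2, 7] Å sanity band. Model-fitting error in tomographic maps varies
slowly along the DNA at the map resolution scale (tens of Å), so iid
per-bp noise — which would also break chain connectivity — is not a
realistic stand-in. What the generator does *not* emulate: curvature of
long arms (straight beyond the wrap), sequence-dependent flexibility,
H1-specific foreign-DNA invasion topologies, and density-map artifacts;
passing recovery tests therefore demonstrate pipeline correctness on the
model family, not robustness to every feature of experimental maps.

## Fibers and condensates

The coarse-grained fiber treats each NCP as a 50 Å hard sphere carrying
the ideal wrapped track. Arm origins move on the track with sampled
unwrapping; arm directions follow the condition's `(alpha, beta)`
distributions; consecutive units are connected by a straight 40-bp linker
collinear with both arms, with a fixed 70° left-handed twist per linker
(the designed linker length is kept even when unwrapping moves the
origins). Placements closer than 100 Å between centers (just below the
smallest observed inter-NCP stacking distance) are resampled, with
escalating backtracking and deterministic whole-build restarts — every
build is reproducible from its seed.

Fiber size is summarised by the arc length of a window-5 moving-average
centerline (contour length) and twice the RMS transverse deviation of the
centers plus the sphere radius (width; no standard definition exists, so
this one is fixed and documented). Stiffness comes from resampling the
centerline into fixed 15-nm segments and fitting
`⟨cos theta(s)⟩ = exp(−s/P)` on the log-correlations over the first decade
of decay; chains that do not decay report a documented cap of 1e5 nm. The
worm-like-chain expression `R_g² = (1/3)PL[1 − (P/L)(1 − e^{−L/P})]`,
`R_h = 0.662 R_g`, and the density `n/((4/3)πR_g³)` (also in µM) complete
the per-fiber metrics.

Condensate density is bracketed two ways: "seamless assembly" (the
condensate is as dense as the average fiber — an upper bound) and "random
docking" of rigid fibers into a 200-nm sphere with an envelope of spheres
at the NCP centers whose radius is half a draw from the condition's
(i, i+2) spacing distribution (a lower bound). Docking is sequential with
uniform random placement, 1000 attempts per fiber, stopping at the first
fiber that cannot be placed.

Two directional claims about these simulations are checked in the test
suite at desk scale (20 fibers × 100 NCPs per condition; docking with 10
fibers × 20 NCPs over 5 seeds): the 50 mM parameter set gives shorter,
narrower, *denser* fibers and denser docked condensates than the 5 mM
set. The absolute published fiber dimensions and condensate
concentrations are not reproducible because the generating dispersions
behind them were never published numerically; only orderings are
asserted. A third directional claim — that suppressing unwrapping
lengthens fibers — turns out to depend on a convention the source
analysis leaves open (how the fixed linker twist composes with origin
variation on the track): under this package's self-consistent convention
(arm angles defined against the local tangent at the sampled origin),
origin variation randomises the effective inter-unit twist and *extends*
the chain, so suppressing it shortens rather than lengthens fibers. The
package documents this sensitivity instead of asserting either sign.

## Conformational classification

Pairwise model similarity is the minimized RMSD under proper-rotation
Kabsch superposition of all trace points, equally weighted (reflections
are excluded to preserve DNA chirality). Single-linkage agglomeration of
the RMSD matrix — whose merge heights equal the sorted minimum-spanning-
tree edge weights — orders the conformations; the dendrogram leaf order is
the display order, exportable as Newick.

## Numerical choices and degenerate inputs

* Wrapped-run detection requires ≥ 20 aligned base pairs; frame fitting
  requires ≥ 40 points and rejects collinear input.
* Angle measurement requires 20 bp (+2 bp guard) of arm beyond each
  boundary and reports `alpha` as `NA` for arms parallel to the Z axis.
* Mixture fits require n ≥ 8 (n ≥ 20 for two components); KDEs use
  Silverman bandwidth by default; KS p-values are asymptotic.
* Zero-variance inputs (identical junctions, constant samples) raise
  errors rather than returning undefined correlations.
* All RNG use is seeded; population seeds are derived from one master
  seed with a fixed linear rule, keeping every derived seed below 2^31.

## Scale of the shipped checks

The test-suite problem sizes are chosen so the whole suite runs in
minutes: parameter recovery uses 200 arrays per preset at 2 Å noise;
persistence-length validation uses 100 chains of 100 segments; salt
comparisons use 20 fibers of 100 NCPs per condition; oracle comparisons
(brute-force superposition, naive single linkage) use ≤ 10 points and
≤ 5 models. These sizes are statements about statistical sufficiency for
the asserted tolerances, and the same generator scales to larger
populations by changing one argument.
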