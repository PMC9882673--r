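# nucarray

Per-particle geometry, statistics and coarse-grained simulation of
nucleosome arrays.

Individual-particle structural models of nucleosome arrays — a 3D
helical-center trace for every DNA base pair plus the placement of each
nucleosome core particle (NCP) — let one quantify chromatin structure
molecule by molecule instead of through ensemble averages: how many base
pairs each NCP has unwrapped ("breathing"), how its two linker-DNA arms
are oriented, how NCPs pack against each other, and what those per-
condition distributions imply for the morphology and density of long
chromatin fibers and condensates. `nucarray` is an R package for exactly
this analysis, for structural biologists working with per-particle
tomographic models or with simulated arrays.

## What it computes

Every NCP is given an orthonormal frame (Z along the superhelical axis of
the ~1.7-turn, 147-bp wrap; Y toward the dyad; X = Y × Z). On that frame
the package measures, per NCP:

* unwrapping deltas at the entry/exit sides (bp, negative = peeled), from
  an 8 Å overlap criterion against the ideal superhelical path
  (radius 41.8 Å, pitch 25 Å) with changepoint-refined boundaries;
* the inter-arm angle θ of the two 20-bp arm vectors and its signed
  projections θ∥ (disc plane; θ∥ < 0 = closed arms) and θ⊥;
* the in-plane wrapping angle α (vs. the local path tangent, positive
  outward) and the bending angle β = arcsin(arm · Z);

and per NCP pair, center distances D(n, n+m) and discoidal-plane
dihedrals φ ∈ [0°, 90°]. Distribution tools fit Gaussian mixtures (EM,
BIC) and kernel densities, convert two-state populations into Boltzmann
energy gaps ΔU = −ln(p_i/p_j) kT, and test dihedrals against the
random-plane null (density sin φ). Conformations are classified by
proper-rotation Kabsch RMSD with single-linkage ordering. A coarse-
grained simulator chains 100-NCP fibers from the measured angle and
unwrapping distributions (fixed 40-bp linkers, 70° left-handed twist per
linker, hard-sphere clash rejection) and analyses them as worm-like
chains: persistence length from tangent autocorrelation at 15-nm
segments, R_g² = (1/3)PL[1 − (P/L)(1 − e^(−L/P))], R_h = 0.662 R_g, and
NCP densities, plus condensate density bounds by seamless assembly vs.
random docking into a 200-nm sphere. A synthetic-array generator with
per-condition presets (mono/di/tri/tetranucleosome at 5 mM Na+,
tetranucleosome at 50 mM Na+ and with linker histone H1) provides
ground-truthed inputs so the entire pipeline runs and validates with no
experimental data.

## Worked example

```r
library(nucarray)

params <- preset_table("tetra_50mM", noise_sd = 2)  # high-salt condition
models <- generate_population(params, 30, seed = 42)
meas   <- measure_models(models)                    # full re-detection
#> <nuca_measurements> 30 models, 120 NCP rows, 180 pair rows

alpha <- c(meas$ncp$alpha_entry_deg, meas$ncp$alpha_exit_deg)
fit_mixture(alpha[is.finite(alpha)], k = 2)
#> <nuca_mixture> k=2, n=240
#>   component 1: weight 0.602, mean -0.89, sd 19.18
#>   component 2: weight 0.398, mean 29.23, sd 8.85

boltzmann_gap(0.398, 0.602)$delta_u_kbt
#> 0.41   # kT between the open and closed arm states

linker_consistency(models)$r
#> -1     # detected linker lengths vs unwrapping angles, 90 junctions

di <- meas$pairs$dihedral_deg[meas$pairs$m == 1]
sin_null_test(di)$statistic
#> 0.169  # consecutive-NCP planes deviate from random mutual orientation
```

The mixture recovers the two wrapping-angle states the preset generates
(major peak near 32° against a broad near-tangential peak, populations
~40/60), the two-state energy gap follows from the populations, the
negative linker-length/unwrapping correlation confirms the detected
intervals conserve the template DNA, and the dihedral KS statistic flags
non-random packing of consecutive NCPs.

The same operations are scriptable from a shell through the installed
entry point (`synth`, `measure`, `stats`, `cluster`, `fiber`, `condense`,
`report` subcommands):

```sh
NUCARRAY="$(Rscript -e 'cat(file.path(find.package("nucarray"), "exec", "nucarray"))')"
"$NUCARRAY" synth --preset mono_5mM -n 47 --seed 1 --out models/
"$NUCARRAY" measure --in models/ --out measured/
"$NUCARRAY" stats --in measured/ --out stats/
```

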