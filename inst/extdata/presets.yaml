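# Generating-distribution presets, one per experimental condition.
# alpha: two-component Gaussian mixture of the wrapping angle (degrees),
#   weights ordered (major component first). Dispersions that were only
#   reported for the mononucleosome condition default to those values
#   (5 deg major, 16 deg minor, 11 deg beta) and the preset is flagged
#   partially_specified.
# deltas: signed unwrapping in bp, negative = peeled DNA.
# spacing_A: every-other-NCP (i, i+2) center distance used by the
#   condensate docking envelope (sd is a package default).
mono_5mM:
  n_ncp: 1
  alpha: {weights: [0.54, 0.46], means: [39, 14], sds: [5, 16]}
  beta: {mean: -9, sd: 11}
  delta_entry: {mean: -5, sd: 5}
  delta_exit: {mean: -11, sd: 13}
  spacing_A: {mean: 265, sd: 30}
  partially_specified: false
di_5mM:
  n_ncp: 2
  alpha: {weights: [0.43, 0.57], means: [32, -8], sds: [5, 16]}
  beta: {mean: -9, sd: 11}
  delta_entry: {mean: -4, sd: 5}
  delta_exit: {mean: -8, sd: 10}
  spacing_A: {mean: 265, sd: 30}
  partially_specified: true
tri_5mM:
  n_ncp: 3
  alpha: {weights: [0.36, 0.64], means: [32, -8], sds: [5, 16]}
  beta: {mean: -9, sd: 11}
  delta_entry: {mean: -7, sd: 7}
  delta_exit: {mean: -10, sd: 11}
  spacing_A: {mean: 265, sd: 30}
  partially_specified: true
tetra_5mM:
  n_ncp: 4
  alpha: {weights: [0.39, 0.61], means: [32, -8], sds: [5, 16]}
  beta: {mean: -9, sd: 11}
  delta_entry: {mean: -4, sd: 8}
  delta_exit: {mean: -14, sd: 12}
  spacing_A: {mean: 265, sd: 30}
  partially_specified: true
tetra_50mM:
  n_ncp: 4
  alpha: {weights: [0.38, 0.62], means: [32, -14], sds: [5, 16]}
  beta: {mean: -4, sd: 11}
  delta_entry: {mean: -4, sd: 9}
  delta_exit: {mean: -9, sd: 8}
  spacing_A: {mean: 114, sd: 30}
  partially_specified: true
tetra_H1_5mM:
  n_ncp: 4
  alpha: {weights: [0.33, 0.67], means: [27, -16], sds: [5, 16]}
  beta: {mean: -1, sd: 11}
  delta_entry: {mean: -6, sd: 8}
  delta_exit: {mean: -17, sd: 19}
  spacing_A: {mean: 213, sd: 30}
  partially_specified: true
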