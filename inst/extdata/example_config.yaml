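# Example pipeline configuration.
population:
  n_nuclei: 5000
  dose_Gy: 1
  foci_per_gray: 15.5
  target_volume_um3: 1.6
  background_mean: 0.6
  background_var: 2.1
  rif_mode: energy_only
  cycling_fraction: 0.2
  n_replicates: 3
  dose_jitter_rel_sd: 0.06
model:
  # override the default calibration with explicit constants if desired
  k1: 0.3165
  k2: 0.8196
  beam_label: Co-60
geometry:
  nucleus: {major_axis: 17, minor_axis: 11, thickness: 2}
  dna_cylinder: {diameter: 2.3, diameter_unit: nm, length: 2.04, length_unit: m}
study:
  doses: [0, 0.5, 1, 2]
  n_per_dose: [25114, 8242, 8993, 9010]
  volumes: [293.7, 8.5, 1.6]
  seed: 1
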