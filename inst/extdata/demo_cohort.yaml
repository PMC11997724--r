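# Demo pipeline configuration: a small synthetic cohort with the default
# planted group structure, sized to run end-to-end in a few minutes.
out_dir: demo_out
seed: 1
bootstrap_b: 100
q: 0.05
synth:
  n_patients: 120
  seed: 1
  grid_shape: [48, 48, 48]
  n_streamlines_per_side: 40
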