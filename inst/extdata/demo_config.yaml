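# Demo configuration for run_pipeline() / inst/scripts/vsdpd.R.
# One analysis window's worth of synthetic data with a prescribed
# mutant-style perturbation (condition b): higher S6 contact probabilities
# and a 2 Angstrom headgroup shift toward S6.
seed: 1
outdir: kvcoupling_demo
simulate:
  n_subunits: 4
  n_frames: 250
  delta_p:
    "354": 0.34
    "358": 0.30
  displacement: 2.0
saltbridge:
  cutoff: 3.2
  pool_subunits: true
energy:
  regionA: [247, 260]
  regionB: [323, 358]
  cutoff: 11
  switch_on: 8
  blocks: 5
  n_frames: 50
statecmp:
  threshold: 0.15
gating:
  v_half_a: -20.0
  v_half_b: -50.0
  z: 2.0
  noise_sd: 0.02
  cycle: [0.56, 0.68, 2.60]
  cycle_se: [0.14, 0.07, 0.13]
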