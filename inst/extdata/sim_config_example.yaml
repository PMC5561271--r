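# Example synthetic-cohort configuration: a small two-group, two-site
# cohort with one seed-coupled frontal network whose coupling increases
# after the task in the first group only, and a clinical score linked to
# the network's true connectivity change.
dims: [14, 14, 12]
n_timepoints: 180
tr_seconds: 2
groups:
  - {label: BPD, "n": 20}
  - {label: NPC, "n": 20}
n_sites: 2
seed_centers_mm:
  - [-9, 0, 0]
  - [9, 0, 0]
seed_radius_mm: 5
ar1_coef: 0.3
rng_seed: 1
networks:
  frontal:
    center_mm: [0, 12, 9]
    radius_mm: 7.5
    n_voxels: 40
    w:
      BPD: [0.1, 0.5]
      NPC: [0.1, 0.1]
clinical_links:
  - {score: BPDSI, network: frontal, target_r: 0.45}
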