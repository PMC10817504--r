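# Example simulation + pipeline configuration.
# Grid: 40 x 40 pixels of 10 m; four monitored years with seven
# acquisitions per vegetation period; damage events list the compartments
# whose NIR reflectance is depressed in a given year.
grid:
  width: 40
  height: 40
  pixel_size: 10
  crs_label: local-metric
years: [2017, 2018, 2019, 2020]
doys: [105, 135, 165, 195, 225, 255, 285]
n_compartments: 12
species_mix: [0.20, 0.15, 0.35, 0.15, 0.15]
noise_sd: 0.02
cloud_prob_clear: 0.4
cloud_max_fraction: 0.25
seed: 42
damage_events:
  - compartment_id: 1
    year: 2017
    damage_type: frost
    severity: 0.7
    affected_fraction: 1.0
  - compartment_id: 2
    year: 2017
    damage_type: drought
    severity: 0.7
    affected_fraction: 1.0
# pipeline parameters
max_cloud_pct: 5
z_threshold: -0.5
ratio_threshold: 30
rf:
  n_trees: 100
  vars_per_split: 10
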