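# Example synthetic-cohort specification for read_cohort_spec().
# Any field omitted here falls back to the package default; see
# ?cohort_spec for units and meanings.
n_homes: 124
seed: 1
urban_fraction: 0.6
urban_aromatic_multiplier: 2.17   # outdoor BTEX/TMB median shift, urban homes
spike_prob: 0.05                  # painting-style episodic aromatic spikes
spike_multiplier: 50
volume_range: [30, 110]           # gross room volume, m^3
occupancy_fraction_range: [0.3, 0.8]
co2_noise_gsd: 1                  # 1 = no noise, exact ACR round trip
date_range: ["2023-03-01", "2024-04-30"]
seasonal_acr:                     # true air change rate, h^-1
  - {season: winter, median: 0.70, gsd: 1.45}
  - {season: spring, median: 1.10, gsd: 1.45}
  - {season: summer, median: 1.20, gsd: 1.45}
  - {season: autumn, median: 0.85, gsd: 1.45}
acr_params:
  g_adult: 0.312                  # CO2 generation, L min^-1
  g_child: 0.174
  co2_outdoor: 450                # ppm
  furnishing_fraction: 0.07
# voc_panel and occupancy_dist accept lists of records in the same style:
# voc_panel:
#   - {voc: limonene, class: monoterpene, indoor_median: 15,
#      indoor_gsd: 2.8, outdoor_median: 0.3, outdoor_gsd: 1.8}
# occupancy_dist:
#   - {n_adults: 2, n_children: 1, prob: 1}
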