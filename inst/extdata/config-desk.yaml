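# Desk-scale end-to-end configuration: phantom simulation, unmixing,
# ROI statistics, cohort simulation, model fit and report.
seed: 42
stages:
  - simulate-phantom
  - unmix
  - roi-stats
  - simulate-cohort
  - fit
  - report
phantom:
  grid: [8, 16, 16]
  spacing: [203, 75, 75]          # um; 203 um slice step
  wavelengths: [680, 730, 800, 924, 930, 968]
  noise_sd: 0.02
  geometry:
    - component: aunr_cell
      level: 1.0
      region: {kind: sphere, center: [4, 8, 8], radius: 4}
    - component: hbo2
      level: 0.6
      region: {kind: box, slices: [1, 8], rows: [1, 16], cols: [1, 8]}
    - component: melanin
      level: 0.3
      region: {kind: box, slices: [1, 2], rows: [1, 16], cols: [1, 16]}
cohort:
  n_treated: 8
  n_control: 2
  means:
    treated: [27, 29, 31]
    control: [18, 17.5, 17]
  sds: {treated: 2, control: 2}
  days: [0, 1, 3]
roi_stats:
  components: [aunr_cell, hbo2]
  fraction: 0.1
fit:
  chains: 4
  tune: 1000
  draws: 2000
  sigma_sharing: per-group
  hdi: 0.95
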