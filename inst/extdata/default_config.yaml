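# Frozen default study configuration.
# Any key may be omitted; omitted keys take the package defaults shown here.
seed: 20190708
map_source: fitted          # fitted | ground_truth
jitter_cv: 0.02             # phantom voxel jitter (coefficient of variation)

cohort:
  n_preterm: 18
  n_term: 7
  preterm:
    ga_mean_weeks: 25.5714286   # 25 + 4
    ga_sd_weeks: 1.8571429      # 1 + 6
    postnatal_mean_days: 94
    postnatal_sd_days: 27.3
    p_male: 0.5
  term:
    ga_mean_weeks: 39.8571429   # 39 + 6
    ga_sd_weeks: 1.2857143      # 1 + 2
    postnatal_mean_days: 17.3
    postnatal_sd_days: 18.3
    p_male: 0.142857
  p_motion: 0.0
  p_devastation: 0.0
  p_pathology_left: 0.08
  p_pathology_right: 0.08

maturation:
  preterm_delay_weeks: 2.0    # ~ one T1 scoring bin at mid-transition
  subject_sd_weeks: 0.9       # between-subject maturational variability

protocol:
  saturation_delays_ms: [150, 700, 1900, 4000]
  echo_times_ms: [13, 35, 60, 100, 140]
  tr_ms: 3309
  saturation_flip_deg: 120
  noise_sigma: 1.6            # PD/50, i.e. SNR 50 at white-matter PD 80
  noise_model: rician

geometry:
  dim: [64, 64, 32]
  spacing_mm: [2, 2, 2]

rater_miss:
  qmap: 0.30
  conventional: 0.40
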