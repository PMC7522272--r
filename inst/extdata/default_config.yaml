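# Default synthetic-study pipeline configuration.
# Run:  Rscript inst/cli/lsfgpwf.R run --config default_config.yaml \
#         --out out --seed 1
out: lsfgpwf_out
seed: 1
study:
  n_rabbits: 10
  heart_rate_bpm: 240
  frame_rate_hz: 30
  acquisition_s: 4
  baseline_sessions: 8
  days: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19,
         20, 21, 22, 23, 24, 25, 26, 27, 28]
  vrp_end_day: 19
  noise_sd: 0.5
  session_cv: 0.03
  nba_effect_size: 0.5
analysis:
  n_frames: 30
  segmentation: otsu
  quantile_q: 0.2
  alpha: 0.05
  phase_windows: [[1, 19], [20, 28]]
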