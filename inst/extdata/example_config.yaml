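# Example configuration for binsrm (any subset of binsrm_config() blocks).
rate: 48000
duration_s: 2.0
calibration:
  spl_ref_rms: 0.05
  spl_ref_db: 65
head:
  itd_90_ms: 0.70
  ild_shelf_db: 12
  shelf_corner_hz: 1500
room:
  environment: anechoic
  t60_s: 1.25
  direct_to_reverberant_db: 0
  tail_coherence: 0.25
ec:
  sigma_delta0: 6.5e-05
  tau0: 0.0016
  sigma_eps0: 0.25
  alpha0: 13
  p: 1.6
  window_ms: 11
selector:
  env_lp_hz: 150
  n_mod_bands: 8
  mod_f_lo: 4
  mod_f_hi: 128
  mod_q: 1
pipeline:
  n_sentences: 10
  n_mc: 10
  calibration_srt_db: -7.0
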