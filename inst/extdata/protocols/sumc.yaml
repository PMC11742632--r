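site_name: SUMC
tr_ms: 4.0
te_ms: 2.0
fa_deg: 60.0
vfa_deg:
- 5.0
- 15.0
- 20.0
- 25.0
vfa_tr_ms: 10.0
vfa_te_ms: 2.0
dt_s: 18.0
duration_min: 20.0
r1_relaxivity: 3.89
contrast_agent: Dotarem
n_frames: 67
injection_time_s: 60.0
n_baseline_frames: ~
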