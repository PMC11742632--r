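site_name: SJH
tr_ms: 5.73
te_ms: 2.78
fa_deg: 60.0
vfa_deg:
- 10.0
- 15.0
- 20.0
- 25.0
- 30.0
vfa_tr_ms: 5.67
vfa_te_ms: 2.78
dt_s: 22.2
duration_min: 22.0
r1_relaxivity: 3.89
contrast_agent: Dotarem
n_frames: 60
injection_time_s: 60.0
n_baseline_frames: ~
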