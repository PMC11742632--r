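site_name: UCLH
tr_ms: 6.17
te_ms: 5.0
fa_deg: 12.0
vfa_deg:
- 2.0
- 6.0
- 12.0
vfa_tr_ms: 6.15
vfa_te_ms: 2.0
dt_s: 7.2
duration_min: 20.0
r1_relaxivity: 3.09
contrast_agent: Prohance
n_frames: 167
injection_time_s: 60.0
n_baseline_frames: ~
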