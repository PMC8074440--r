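# Physiological plausibility ranges used to flag studies for human review.
# These are editable conventions, not normative values; override per study.
lv_ef_pct: [20, 80]
rv_ef_pct: [20, 75]
lv_edv_ml: [50, 350]
lv_esv_ml: [10, 250]
lv_sv_ml: [20, 180]
lv_mass_g: [40, 280]
rv_edv_ml: [40, 350]
rv_esv_ml: [10, 250]
rv_sv_ml: [20, 180]
scar_pct: [0, 60]
mean_t1_ms: [800, 1500]
mean_t1post_ms: [250, 750]
mean_t2_ms: [30, 90]
net_flow_ml: [30, 150]
backward_flow_ml: [0, 40]
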