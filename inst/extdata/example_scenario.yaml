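# Nominal bench scenario: 8.5 kW/m2 radiant exposure for 300 s, then
# 2500 s of resting recovery at 30 degC / 65% RH, 6.4 mm vertical air gap.
# Any omitted key takes its packaged default (see ?scenario_config).
nominal_flux_kW_m2: 8.5
exposure_s: 300
cooling_s: 2500
ambient_C: 30
rh_pct: 65
gap_mm: 6.4
metabolic_W_m2: 290
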