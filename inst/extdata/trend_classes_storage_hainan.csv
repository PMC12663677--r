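abbreviation,proportion_pct,area_km2
ESI,7.23,2449.82
SI,1.38,467.78
NSC,89.85,30441.53
SD,1.54,522.15
ESD,0.00,0.00
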