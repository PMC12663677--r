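abbreviation,proportion_pct,area_km2
ESI,18.91,6406.04
SI,4.56,1545.57
NSC,55.04,18647.01
SD,5.28,1787.97
ESD,16.22,5494.70
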