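abbreviation,proportion_pct,area_km2
ESI,21.43,7259.79
SI,5.84,1978.41
NSC,57.19,19377.06
SD,4.94,1672.85
ESD,10.61,3593.18
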