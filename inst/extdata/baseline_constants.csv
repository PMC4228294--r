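quantity,value,units
total_csf_volume,150,mL
sas_csf_volume,125,mL
ventricular_csf_volume,25,mL
daily_csf_production,580,mL/day
metabolic_water_rate,34,uL/min
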