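experiment,injection_mOsm,duration_days,surface_increase_pct,volume_increase_pct,agent
E2,2400,7,2.1,NA,sucrose
E6,307,12,NA,0,dextran40k
E6,328,12,NA,42,dextran
E6,337,12,NA,83,dextran10k
E6,664,12,NA,72,FGF2
E6,337,15,NA,125,dextran10k
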