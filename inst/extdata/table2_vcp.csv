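experiment,perfusion_rate_uL_min,injection_mOsm,bulk_flow_uL_min,location
E1,77,6,0.0,ventricle
E1,77,320,24.9,ventricle
E1,77,780,88.0,ventricle
E2,NA,320,12.6,ventricle
E2,NA,950,24.8,ventricle
E3,77,290,49.9,serum
E3,77,322,22.7,serum
E3,77,360,0.0,serum
E4,77,320,21.8,serum
E4,77,60,54.9,serum
E5,12.6,320,12.6,serum
E5,12.6,1110,0.9,serum
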