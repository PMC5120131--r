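patient,NPSM,NPSM2,PSM
P1,30.97,62.14,68.38
P2,11.10,46.56,65.26
P3,18.51,52.79,71.50
P4,15.39,30.30,30.30
P5,30.3,71.50,71.50
P6,9.16,40.33,59.03
P7,19.22,59.03,55.91
P8,30.30,71.50,71.50
P9,12.27,30.30,30.30
P10,9.17,22.74,30.30
P11,19.22,43.44,65.26
P12,19.22,27.86,30.97
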