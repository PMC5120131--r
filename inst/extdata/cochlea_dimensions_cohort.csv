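patient,A_mm,B_mm,H_mm
P1,9.61,7.00,4.94
P2,7.81,5.49,5.27
P3,9.72,6.85,5.13
P4,8.91,6.59,4.77
P5,9.00,6.80,4.76
P6,9.85,7.47,4.01
P7,8.91,6.53,4.50
P8,8.75,6.95,5.01
P9,8.79,6.28,4.805
P10,8.88,6.68,4.94
P11,7.50,5.70,4.32
P12,8.98,6.95,4.99
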