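structure,conductivity_S_per_m
electrode,1000
scala_media,1.67
scala_tympani,1.43
scala_vestibuli,1.43
basilar_membrane,0.0625
reissner_membrane,0.00098
nerve,0.3
bone,0.02
silicone,0.099
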