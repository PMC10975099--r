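drug_u,drug_v,rater,severity_code
C02_001,C04_001,edic_a,0
C02_001,C04_002,edic_a,2
C02_002,C04_001,edic_a,3
C02_002,C04_002,edic_a,0
C02_001,C04_001,edic_b,0
C02_001,C04_002,edic_b,2
C02_002,C04_001,edic_b,3
C02_002,C04_002,edic_b,0
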