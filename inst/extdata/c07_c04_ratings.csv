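drug_u,drug_v,rater,severity_code
C04_001,C07_001,edic_a,0
C04_002,C07_001,edic_a,0
C04_003,C07_001,edic_a,0
C04_004,C07_001,edic_a,0
C04_001,C07_002,edic_a,0
C04_002,C07_002,edic_a,0
C04_003,C07_002,edic_a,0
C04_004,C07_002,edic_a,0
C04_001,C07_003,edic_a,0
C04_002,C07_003,edic_a,0
C04_003,C07_003,edic_a,0
C04_004,C07_003,edic_a,0
C04_001,C07_004,edic_a,0
C04_002,C07_004,edic_a,0
C04_003,C07_004,edic_a,0
C04_004,C07_004,edic_a,0
C04_001,C07_005,edic_a,0
C04_002,C07_005,edic_a,0
C04_003,C07_005,edic_a,0
C04_004,C07_005,edic_a,0
C04_001,C07_006,edic_a,0
C04_002,C07_006,edic_a,0
C04_003,C07_006,edic_a,0
C04_004,C07_006,edic_a,0
C04_001,C07_007,edic_a,0
C04_002,C07_007,edic_a,0
C04_003,C07_007,edic_a,0
C04_004,C07_007,edic_a,0
C04_001,C07_008,edic_a,0
C04_002,C07_008,edic_a,0
C04_003,C07_008,edic_a,0
C04_004,C07_008,edic_a,0
C04_001,C07_009,edic_a,0
C04_002,C07_009,edic_a,0
C04_003,C07_009,edic_a,0
C04_004,C07_009,edic_a,0
C04_001,C07_010,edic_a,0
C04_002,C07_010,edic_a,0
C04_003,C07_010,edic_a,0
C04_004,C07_010,edic_a,0
C04_001,C07_011,edic_a,0
C04_002,C07_011,edic_a,0
C04_003,C07_011,edic_a,0
C04_004,C07_011,edic_a,0
C04_001,C07_012,edic_a,0
C04_002,C07_012,edic_a,0
C04_003,C07_012,edic_a,0
C04_004,C07_012,edic_a,0
C04_001,C07_013,edic_a,0
C04_002,C07_013,edic_a,0
C04_003,C07_013,edic_a,0
C04_004,C07_013,edic_a,0
C04_001,C07_001,edic_b,0
C04_002,C07_001,edic_b,0
C04_003,C07_001,edic_b,0
C04_004,C07_001,edic_b,0
C04_001,C07_002,edic_b,0
C04_002,C07_002,edic_b,0
C04_003,C07_002,edic_b,0
C04_004,C07_002,edic_b,0
C04_001,C07_003,edic_b,0
C04_002,C07_003,edic_b,0
C04_003,C07_003,edic_b,0
C04_004,C07_003,edic_b,0
C04_001,C07_004,edic_b,0
C04_002,C07_004,edic_b,0
C04_003,C07_004,edic_b,0
C04_004,C07_004,edic_b,0
C04_001,C07_005,edic_b,0
C04_002,C07_005,edic_b,0
C04_003,C07_005,edic_b,0
C04_004,C07_005,edic_b,0
C04_001,C07_006,edic_b,0
C04_002,C07_006,edic_b,0
C04_003,C07_006,edic_b,0
C04_004,C07_006,edic_b,0
C04_001,C07_007,edic_b,0
C04_002,C07_007,edic_b,0
C04_003,C07_007,edic_b,2
C04_004,C07_007,edic_b,2
C04_001,C07_008,edic_b,2
C04_002,C07_008,edic_b,2
C04_003,C07_008,edic_b,2
C04_004,C07_008,edic_b,2
C04_001,C07_009,edic_b,2
C04_002,C07_009,edic_b,2
C04_003,C07_009,edic_b,2
C04_004,C07_009,edic_b,2
C04_001,C07_010,edic_b,2
C04_002,C07_010,edic_b,2
C04_003,C07_010,edic_b,2
C04_004,C07_010,edic_b,2
C04_001,C07_011,edic_b,2
C04_002,C07_011,edic_b,2
C04_003,C07_011,edic_b,2
C04_004,C07_011,edic_b,2
C04_001,C07_012,edic_b,2
C04_002,C07_012,edic_b,2
C04_003,C07_012,edic_b,2
C04_004,C07_012,edic_b,2
C04_001,C07_013,edic_b,2
C04_002,C07_013,edic_b,2
C04_003,C07_013,edic_b,2
C04_004,C07_013,edic_b,2
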