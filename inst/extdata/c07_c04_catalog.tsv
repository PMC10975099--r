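drug_id	name	category	primary_subcategory	atc_codes
C07_001	synthetic beta blocker 1	C	C07	C07
C07_002	synthetic beta blocker 2	C	C07	C07
C07_003	synthetic beta blocker 3	C	C07	C07
C07_004	synthetic beta blocker 4	C	C07	C07
C07_005	synthetic beta blocker 5	C	C07	C07
C07_006	synthetic beta blocker 6	C	C07	C07
C07_007	synthetic beta blocker 7	C	C07	C07
C07_008	synthetic beta blocker 8	C	C07	C07
C07_009	synthetic beta blocker 9	C	C07	C07
C07_010	synthetic beta blocker 10	C	C07	C07
C07_011	synthetic beta blocker 11	C	C07	C07
C07_012	synthetic beta blocker 12	C	C07	C07
C07_013	synthetic beta blocker 13	C	C07	C07
C04_001	synthetic peripheral vasodilator 1	C	C04	C04
C04_002	synthetic peripheral vasodilator 2	C	C04	C04
C04_003	synthetic peripheral vasodilator 3	C	C04	C04
C04_004	synthetic peripheral vasodilator 4	C	C04	C04
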