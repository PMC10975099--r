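drug_id	name	category	primary_subcategory	atc_codes
C02_001	synthetic drug 1	C	C02	C02
C02_002	synthetic drug 2	C	C02	C02
C04_001	synthetic drug 3	C	C04	C04
C04_002	synthetic drug 4	C	C04	C04
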