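group	old_symbol	fish	amphibian	reptile	bird	mammal
ADGRA1	Gpr123	present	present	present	present	present
ADGRA2	Gpr124	present	present	present	present	present
ADGRA3	Gpr125	present	present	present	present	present
ADGRB1	Bai1	present	present	present	present	present
ADGRB2	Bai2	present	present	present	present	present
ADGRB3	Bai3	present	present	present	present	present
ADGRC1	Celsr1	present	present	present	present	present
ADGRC2	Celsr2	present	present	present	present	present
ADGRC3	Celsr3	present	present	present	present	present
ADGRD1	Gpr133	present	present	present	present	present
ADGRD2	Gpr144	present	present	present	present	present
ADGRE1	Emr1	present	present	present	absent	present
ADGRE2	Emr2	present	present	present	absent	present
ADGRE3	Emr3	present	present	present	absent	present
ADGRE4	Emr4	present	present	present	absent	pseudogene
ADGRE5	Cd97	present	present	present	absent	present
ADGRF1	Gpr110	present	present	present	present	present
ADGRF2	Gpr111	present	present	present	present	present
ADGRF3	Gpr113	present	present	present	absent	present
ADGRF4	Gpr115	present	present	present	present	present
ADGRF5	Gpr116	present	present	present	present	present
ADGRG1	Gpr56	present	present	present	present	present
ADGRG2	Gpr64	present	present	present	present	present
ADGRG3	Gpr97	present	present	present	present	present
ADGRG4	Gpr112	present	present	present	present	present
ADGRG5	Gpr114	present	present	present	present	present
ADGRG6	Gpr126	present	present	present	present	present
ADGRG7	Gpr128	present	present	absent	absent	present
ADGRL1	Lphn1	present	present	present	present	present
ADGRL2	Lphn2	present	present	present	present	present
ADGRL3	Lphn3	present	present	present	present	present
ADGRL4	Eltd1	present	present	present	present	present
ADGRV1	VLGR1	present	present	present	present	present
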