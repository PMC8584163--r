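name_v3	family_v3	name_v2	old_symbol	pseudogene
ADGRA1	ADGRA	ADGRA1	Gpr123	FALSE
ADGRA2	ADGRA	ADGRA3	Gpr125	FALSE
ADGRA3	ADGRA	ADGRA2	Gpr124	FALSE
ADGRB1	ADGRB	ADGRB1	Bai1	FALSE
ADGRB2	ADGRB	ADGRB3	Bai3	FALSE
ADGRB3	ADGRB	ADGRB2	Bai2	FALSE
ADGRC1	ADGRC	ADGRC1	Celsr1	FALSE
ADGRC2	ADGRC	ADGRC2	Celsr2	FALSE
ADGRC3	ADGRC	ADGRC3	Celsr3	FALSE
ADGRD1	ADGRD	ADGRD1	Gpr133	FALSE
ADGRD2	ADGRD	ADGRD2	Gpr144	FALSE
ADGRE1	ADGRE	ADGRG7	Gpr128	FALSE
ADGRF1	ADGRF	ADGRF3	Gpr113	FALSE
ADGRF2a	ADGRF	ADGRF1	Gpr110	FALSE
ADGRF2b	ADGRF	ADGRF5	Gpr116	FALSE
ADGRF2c	ADGRF	ADGRF2	Gpr111	FALSE
ADGRF2d	ADGRF	ADGRF4	Gpr115	FALSE
ADGRG1	ADGRG	ADGRG2	Gpr64	FALSE
ADGRG2	ADGRG	ADGRG6	Gpr126	FALSE
ADGRG3	ADGRG	ADGRG4	Gpr112	FALSE
ADGRG4a	ADGRG	ADGRG3	Gpr97	FALSE
ADGRG4b	ADGRG	ADGRG1	Gpr56	FALSE
ADGRG4c	ADGRG	ADGRG5	Gpr114	FALSE
ADGRL1	ADGRL	ADGRL1	Lphn1	FALSE
ADGRL2	ADGRL	ADGRL2	Lphn2	FALSE
ADGRL3	ADGRL	ADGRL3	Lphn3	FALSE
ADGRL4	ADGRL	ADGRL4	Eltd1	FALSE
ADGRL5	ADGRL	ADGRE5	Cd97	FALSE
ADGRL6a	ADGRL	ADGRE1	Emr1	FALSE
ADGRL6b	ADGRL	ADGRE2	Emr2	FALSE
ADGRL6c	ADGRL	ADGRE3	Emr3	FALSE
ADGRL6d	ADGRL	ADGRE4	Emr4	TRUE
ADGRV1	ADGRV	ADGRV1	VLGR1	FALSE
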