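group	one_to_one	multiplicity
ADGRA1	TRUE	1
ADGRA2	TRUE	1
ADGRA3	TRUE	1
ADGRB1	TRUE	1
ADGRB2	TRUE	1
ADGRB3	TRUE	1
ADGRC1	TRUE	1
ADGRC2	TRUE	1
ADGRC3	TRUE	1
ADGRD1	TRUE	1
ADGRD2	TRUE	1
ADGRL1	TRUE	1
ADGRL2	TRUE	1
ADGRL3	TRUE	1
ADGRL4	TRUE	1
ADGRV1	TRUE	1
ADGRG2	TRUE	1
ADGRG4	TRUE	1
ADGRG6	TRUE	1
ADGRE1-5	FALSE	2
ADGRF1-5	FALSE	2
ADGRG1/3/5	FALSE	2
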