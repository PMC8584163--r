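name	start	end
TM1	10	35
TM2	40	65
TM3	70	95
TM4	100	120
TM5	125	150
TM6	155	175
TM7	180	200
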