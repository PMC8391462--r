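alias	class_family
SINE/Alu	SINE/Alu
Alu	SINE/Alu
SINE/AluY	SINE/Alu
LINE/L1	LINE/L1
L1	LINE/L1
Line/L1	LINE/L1
Low_complexity	Low_complexity
Low complexity	Low_complexity
Simple_repeat	Simple_repeat
Simple repeat	Simple_repeat
LINE/L2	LINE/L2
SINE/MIR	SINE/MIR
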