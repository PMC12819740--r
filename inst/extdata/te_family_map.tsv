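prefix	family	te_class
Alu	Alu	SINE
FLAM	Alu	SINE
MIR	MIR	SINE
L1	L1	LINE
L2	L2	LINE
L3	L3	LINE
HERV	ERV	LTR
LTR	ERV	LTR
MER4	ERV	LTR
ERV	ERV	LTR
MLT	ERV	LTR
THE1	ERV	LTR
Charlie	DNA	DNA
Tigger	DNA	DNA
MER	DNA	DNA
hAT	DNA	DNA
SVA	other	other
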