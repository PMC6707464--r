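lineage	parent	origin	divergence	label
B	NA	101000	NA	African
CT	NA	101000	77000	both
DE	CT	77000	73000	both
CF	CT	77000	76000	both
C	CF	76000	NA	non-African
FT	CF	76000	57000	non-African
E	DE	73000	59000	African
D0D	DE	73000	71000	both
D0	D0D	71000	2500	African
D	D0D	71000	NA	non-African
E-M35	E	47000	28500	both
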