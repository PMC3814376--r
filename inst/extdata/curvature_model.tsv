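dinucleotide	roll
AA	0.1
AC	1.6
AG	2.6
AT	0.4
CA	6.5
CC	3.0
CG	6.8
CT	2.6
GA	2.4
GC	4.1
GG	3.0
GT	1.6
TA	7.2
TC	2.4
TG	6.5
TT	0.1
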