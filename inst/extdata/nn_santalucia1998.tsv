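# SantaLucia (1998) unified nearest-neighbour parameters for DNA/DNA duplexes.
# Transcribed from the primary literature. Units: dH in cal/mol, dS in cal/(mol.K).
# Stacks are written 5'->3' on the top strand; the table is strand-symmetric
# (each stack equals its reverse complement). Initiation is per-terminal:
# term_AT applies to an A.T-closing end, term_GC to a G.C-closing end.
type	key	dH_cal_mol	dS_cal_molK
stack	AA	-7900	-22.2
stack	AC	-8400	-22.4
stack	AG	-7800	-21.0
stack	AT	-7200	-20.4
stack	CA	-8500	-22.7
stack	CC	-8000	-19.9
stack	CG	-10600	-27.2
stack	CT	-7800	-21.0
stack	GA	-8200	-22.2
stack	GC	-9800	-24.4
stack	GG	-8000	-19.9
stack	GT	-8400	-22.4
stack	TA	-7200	-21.3
stack	TC	-8200	-22.2
stack	TG	-8500	-22.7
stack	TT	-7900	-22.2
init	.	0	0
term_AT	.	2300	4.1
term_GC	.	100	-2.8
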