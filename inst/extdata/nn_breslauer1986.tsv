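# Breslauer et al. (1986) nearest-neighbour parameters for DNA/DNA duplexes.
# Transcribed from the primary literature. Units: dH in cal/mol, dS in cal/(mol.K).
# Strand-symmetric stack table; duplex initiation is a single entropic term
# (the common implementation convention), no per-terminal corrections.
type	key	dH_cal_mol	dS_cal_molK
stack	AA	-9100	-24.0
stack	AC	-6500	-17.3
stack	AG	-7800	-20.8
stack	AT	-8600	-23.9
stack	CA	-5800	-12.9
stack	CC	-11000	-26.6
stack	CG	-11900	-27.8
stack	CT	-7800	-20.8
stack	GA	-5600	-13.5
stack	GC	-11100	-26.7
stack	GG	-11000	-26.6
stack	GT	-6500	-17.3
stack	TA	-6000	-16.9
stack	TC	-5600	-13.5
stack	TG	-5800	-12.9
stack	TT	-9100	-24.0
init	.	0	-10.8
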