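# Synthetic benchmark table for the miniCDC fixture: expected phenotypes
# are the fixture's designed outcomes, used to verify the benchmark
# machinery end to end.
label	deletions	locks	overexpress	expected_viability	expected_stage
wildtype				viable
cln3	Cln3			lethal	G1
sbf	SBF			lethal	G1
sic1	Sic1			viable
far1	Far1			viable
bys1	Bys1			viable
clb2	Clb2			lethal	G2/M
cdc14	Cdc14			lethal	M
chs2	Chs2			lethal
sic1-stable		Sic1_[t2]-P=0		lethal	G1
far1-active		Far1_[s1]-P=1		lethal	G1
sbf-mimetic		SBF_[r1]-P=1		viable
CLN2-oe			Cln2	viable
cln3-sbf-mimetic	Cln3	SBF_[r1]-P=1		viable
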