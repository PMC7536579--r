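variant	original_class	zone	exon	gnomad_count	co_occurring_pathogenic	provenance
p.Asn62Ser	4	BENIGN	2	33	FALSE	printed
p.Ala161Thr	4	BENIGN	3	12	FALSE	printed
p.Ala174Val	4	INTERMEDIATE_T2D_RISK	3	60	FALSE	count_constructed
p.Pro291Ser	4	INTERMEDIATE_T2D_RISK	5	45	FALSE	count_constructed
p.Gly606Ser	4	BENIGN	10	12	FALSE	printed
p.His469Tyr	4	BENIGN	7	32	TRUE	printed
p.Asp526Asn	4	DAMAGING_MODY	8	5	FALSE	printed
p.Gly47Arg	4	DAMAGING_MODY	2	1	FALSE	constructed
p.Met412Thr	4	DAMAGING_MODY	6	0	FALSE	constructed
p.Arg131Gln	4	DAMAGING_MODY	3	2	FALSE	constructed
p.Thr10Met	4	DAMAGING_MODY	1	1	FALSE	constructed
p.Pro112Leu	5	DAMAGING_MODY	2	0	FALSE	constructed
p.Arg203His	5	DAMAGING_MODY	4	1	FALSE	constructed
p.Ala116Val	4	DAMAGING_MODY	2	0	FALSE	constructed
p.Pro379Thr	4	DAMAGING_MODY	6	0	FALSE	constructed
p.Ala276Asp	4	DAMAGING_MODY	4	1	FALSE	constructed
p.Arg159Trp	5	DAMAGING_MODY	3	0	FALSE	constructed
p.Thr260Met	4	DAMAGING_MODY	4	2	FALSE	constructed
p.Arg171Gln	4	DAMAGING_MODY	3	1	FALSE	constructed
p.Ile27Leu	2	BENIGN	1	4000	FALSE	constructed
p.Gly31Asp	2	BENIGN	1	800	FALSE	constructed
p.Glu48Lys	2	BENIGN	2	300	FALSE	constructed
p.Ala97Val	2	BENIGN	2	500	FALSE	constructed
p.Ala98Val	2	BENIGN	2	900	FALSE	constructed
p.Gln100Lys	2	BENIGN	2	250	FALSE	constructed
p.Arg114His	2	BENIGN	2	400	FALSE	constructed
p.Leu389Val	2	BENIGN	6	650	FALSE	constructed
p.Ser487Asn	2	BENIGN	7	3000	FALSE	constructed
p.Met490Thr	2	BENIGN	8	200	FALSE	constructed
p.His514Arg	2	BENIGN	8	150	FALSE	constructed
p.Thr515Lys	2	BENIGN	8	180	FALSE	constructed
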