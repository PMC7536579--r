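variant	original_class	zone	exon	gnomad_count	co_occurring_pathogenic	provenance
p.Tyr322Cys	3	INTERMEDIATE_T2D_RISK	5	15	FALSE	count_constructed
p.Thr354Met	3	INTERMEDIATE_T2D_RISK	5	7	FALSE	printed
p.Thr441Lys	3	INTERMEDIATE_T2D_RISK	7	18	TRUE	printed
p.Asp526Asn	3	DAMAGING_MODY	8	5	FALSE	printed
p.His582Arg	3	DAMAGING_MODY	9	14	FALSE	printed
p.Ala276Asp	4	DAMAGING_MODY	4	1	FALSE	count_constructed
p.Ala586Thr	2	DAMAGING_MODY	9	20	FALSE	class_constructed
p.Ile27Leu	1	BENIGN	1	4000	FALSE	constructed
p.Gly31Asp	2	BENIGN	1	800	FALSE	constructed
p.Glu48Lys	2	BENIGN	2	300	FALSE	constructed
p.Ala97Val	2	BENIGN	2	500	FALSE	constructed
p.Gln100Lys	2	BENIGN	2	250	FALSE	constructed
p.Arg114His	2	BENIGN	2	400	FALSE	constructed
p.Leu389Val	2	BENIGN	6	650	FALSE	constructed
p.Ser487Asn	2	BENIGN	7	3000	FALSE	constructed
p.Met490Thr	2	BENIGN	8	200	FALSE	constructed
p.His514Arg	2	BENIGN	8	150	FALSE	constructed
p.Thr515Lys	2	BENIGN	8	180	FALSE	constructed
p.His577Asp	2	BENIGN	9	220	FALSE	constructed
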