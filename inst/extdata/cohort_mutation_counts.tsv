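cohort	n_individuals	n_mutations	n_tfbs_mutations
Liver	315	3746554	1924
Pancreas	426	2954823	1260
LungAdenoma	24	1446336	680
Breast	119	647695	388
Prostate	145	449313	223
LymphomaBcell	68	425048	183
Medulloblastoma	100	124941	55
PilocyticAstrocytoma	340	96515	51
CLL	29	52786	8
ALL	1	7741	8
AML	7	6828	2
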