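gene	species	n_samples	n_sequences	n_polymorphisms	n_specific_polymorphisms	n_haplotypes	n_specific_haplotypes
COI	canadensis	24	24	11	7	11	10
COI	glaucus	56	56	18	10	19	15
COI	appalachiensis	28	28	8	3	7	4
KET	canadensis	20	22	37	25	21	17
KET	glaucus	18	18	20	18	15	13
KET	appalachiensis	17	19	30	15	11	8
TH	canadensis	21	21	6	4	8	2
TH	glaucus	34	34	24	14	27	25
TH	appalachiensis	35	35	23	8	19	12
TPI	canadensis	25	27	57	53	20	17
TPI	glaucus	30	30	19	9	22	20
TPI	appalachiensis	16	17	21	9	10	7
PER	canadensis	25	25	8	2	10	4
PER	glaucus	32	32	5	3	30	27
PER	appalachiensis	19	19	21	16	9	5
LDH	canadensis	26	26	46	19	26	23
LDH	glaucus	28	28	38	23	28	27
LDH	appalachiensis	16	16	49	15	14	11
PAH	canadensis	20	27	46	21	26	23
PAH	glaucus	20	24	109	43	24	23
PAH	appalachiensis	18	19	100	14	15	12
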