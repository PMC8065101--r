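sample_id	chrom	pos	ref	alt	gene	consequence	origin	vaf_tumour	vaf_germline	tri_context
PALB2_T01	16	23646191	GA	G	PALB2	frameshift	germline	0.85	0.5	NA
PALB2_T02	16	23646191	G	A	PALB2	splice_donor	germline	0.85	0.5	NA
PALB2_T03	16	23646191	G	A	PALB2	splice_acceptor	germline	0.51	0.5	NA
PALB2_T03	16	23646241	C	T	PALB2	stop_gained	somatic	0.35	0	NA
PALB2_T04	16	23646191	G	A	PALB2	stop_gained	germline	0.51	0.5	NA
PALB2_T04	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
PALB2_T05	16	23646191	GA	G	PALB2	frameshift	germline	0.51	0.5	NA
PALB2_T05	3	178936091	G	A	PIK3CA	missense	somatic	0.4	0	NA
PALB2_T06	16	23646191	G	A	PALB2	splice_donor	germline	0.51	0.5	NA
PALB2_T07	16	23646191	G	A	PALB2	splice_acceptor	somatic	0.35	0	NA
PALB2_T07	3	178936091	G	A	PIK3CA	missense	somatic	0.4	0	NA
PALB2_T08	16	23646191	G	A	PALB2	stop_gained	somatic	0.35	0	NA
PALB2_T09	16	23646191	GA	G	PALB2	frameshift	somatic	0.35	0	NA
BRCA1_T01	17	41245000	GA	G	BRCA1	frameshift	germline	0.85	0.5	NA
BRCA1_T01	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T02	17	41245000	G	A	BRCA1	splice_donor	germline	0.85	0.5	NA
BRCA1_T02	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T03	17	41245000	G	A	BRCA1	splice_acceptor	germline	0.85	0.5	NA
BRCA1_T03	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T04	17	41245000	G	A	BRCA1	stop_gained	germline	0.85	0.5	NA
BRCA1_T04	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T05	17	41245000	GA	G	BRCA1	frameshift	germline	0.85	0.5	NA
BRCA1_T05	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T06	17	41245000	G	A	BRCA1	splice_donor	germline	0.85	0.5	NA
BRCA1_T06	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T07	17	41245000	G	A	BRCA1	splice_acceptor	germline	0.85	0.5	NA
BRCA1_T07	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T08	17	41245000	G	A	BRCA1	stop_gained	germline	0.51	0.5	NA
BRCA1_T08	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T09	17	41245000	GA	G	BRCA1	frameshift	germline	0.51	0.5	NA
BRCA1_T09	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T10	17	41245000	G	A	BRCA1	splice_donor	germline	0.51	0.5	NA
BRCA1_T10	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA1_T11	17	41245000	G	A	BRCA1	splice_acceptor	somatic	0.35	0	NA
BRCA1_T11	3	178936091	G	A	PIK3CA	missense	somatic	0.4	0	NA
BRCA1_T12	17	41245000	G	A	BRCA1	stop_gained	somatic	0.35	0	NA
BRCA1_T12	3	178936091	G	A	PIK3CA	missense	somatic	0.4	0	NA
BRCA1_T13	17	41245000	GA	G	BRCA1	frameshift	somatic	0.35	0	NA
BRCA1_T13	3	178936091	G	A	PIK3CA	missense	somatic	0.4	0	NA
BRCA1_T14	17	41245000	G	A	BRCA1	splice_donor	somatic	0.35	0	NA
BRCA1_T14	3	178936091	G	A	PIK3CA	missense	somatic	0.4	0	NA
BRCA1_T15	17	41245000	G	A	BRCA1	splice_acceptor	somatic	0.35	0	NA
BRCA1_T16	17	41245000	G	A	BRCA1	stop_gained	somatic	0.35	0	NA
BRCA2_T01	13	32907000	GA	G	BRCA2	frameshift	germline	0.85	0.5	NA
BRCA2_T01	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA2_T02	13	32907000	G	A	BRCA2	splice_donor	germline	0.85	0.5	NA
BRCA2_T02	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA2_T03	13	32907000	G	A	BRCA2	splice_acceptor	germline	0.85	0.5	NA
BRCA2_T03	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA2_T04	13	32907000	G	A	BRCA2	stop_gained	germline	0.85	0.5	NA
BRCA2_T04	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA2_T05	13	32907000	GA	G	BRCA2	frameshift	germline	0.85	0.5	NA
BRCA2_T05	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA2_T06	13	32907000	G	A	BRCA2	splice_donor	germline	0.85	0.5	NA
BRCA2_T06	17	7577538	C	T	TP53	missense	somatic	0.4	0	NA
BRCA2_T07	13	32907000	G	A	BRCA2	splice_acceptor	germline	0.85	0.5	NA
BRCA2_T07	3	178936091	G	A	PIK3CA	missense	somatic	0.4	0	NA
BRCA2_T08	13	32907000	G	A	BRCA2	stop_gained	germline	0.51	0.5	NA
BRCA2_T08	3	178936091	G	A	PIK3CA	missense	somatic	0.4	0	NA
BRCA2_T09	13	32907000	GA	G	BRCA2	frameshift	germline	0.51	0.5	NA
BRCA2_T10	13	32907000	G	A	BRCA2	splice_donor	germline	0.51	0.5	NA
BRCA2_T11	13	32907000	G	A	BRCA2	splice_acceptor	germline	0.51	0.5	NA
BRCA2_T12	13	32907000	G	A	BRCA2	stop_gained	somatic	0.35	0	NA
BRCA2_T13	13	32907000	GA	G	BRCA2	frameshift	somatic	0.35	0	NA
BRCA2_T14	13	32907000	G	A	BRCA2	splice_donor	somatic	0.35	0	NA
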