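sample_id	chromosome	start.pos	end.pos	A	B
PALB2_T01	16	13646191	33646191	2	0
PALB2_T02	16	13646191	33646191	2	0
PALB2_T03	16	13646191	33646191	1	1
PALB2_T04	16	13646191	33646191	1	1
PALB2_T05	16	13646191	33646191	1	1
PALB2_T06	16	13646191	33646191	1	1
PALB2_T07	16	13646191	33646191	1	1
PALB2_T08	16	13646191	33646191	1	1
PALB2_T09	16	13646191	33646191	1	1
BRCA1_T01	17	31245000	51245000	2	0
BRCA1_T02	17	31245000	51245000	2	0
BRCA1_T03	17	31245000	51245000	2	0
BRCA1_T04	17	31245000	51245000	2	0
BRCA1_T05	17	31245000	51245000	2	0
BRCA1_T06	17	31245000	51245000	2	0
BRCA1_T07	17	31245000	51245000	2	0
BRCA1_T08	17	31245000	51245000	1	1
BRCA1_T09	17	31245000	51245000	1	1
BRCA1_T10	17	31245000	51245000	1	1
BRCA1_T11	17	31245000	51245000	1	1
BRCA1_T12	17	31245000	51245000	1	1
BRCA1_T13	17	31245000	51245000	1	1
BRCA1_T14	17	31245000	51245000	1	1
BRCA1_T15	17	31245000	51245000	1	1
BRCA1_T16	17	31245000	51245000	1	1
BRCA2_T01	13	22907000	42907000	2	0
BRCA2_T02	13	22907000	42907000	2	0
BRCA2_T03	13	22907000	42907000	2	0
BRCA2_T04	13	22907000	42907000	2	0
BRCA2_T05	13	22907000	42907000	2	0
BRCA2_T06	13	22907000	42907000	2	0
BRCA2_T07	13	22907000	42907000	2	0
BRCA2_T08	13	22907000	42907000	1	1
BRCA2_T09	13	22907000	42907000	1	1
BRCA2_T10	13	22907000	42907000	1	1
BRCA2_T11	13	22907000	42907000	1	1
BRCA2_T12	13	22907000	42907000	1	1
BRCA2_T13	13	22907000	42907000	1	1
BRCA2_T14	13	22907000	42907000	1	1
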