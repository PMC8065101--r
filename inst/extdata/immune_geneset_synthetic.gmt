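immune_infiltrate_synthetic	synthetic stand-in immune signature	CD8A	CD3D	CD3E	CD2	GZMB	GZMK	GZMH	PRF1	NKG7	KLRB1	KLRD1	CCL5	CXCL9	CXCL10	IDO1	LAG3	TIGIT	CTLA4	PDCD1	IFNG
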