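metabolite_id	gene	direction
HMDB0000641	GLUL	producing
HMDB0000641	GLS	consuming
HMDB0000641	GLS2	consuming
HMDB0000148	GLS	producing
HMDB0000148	GOT1	producing
HMDB0000148	GLUL	consuming
HMDB0001999	FADS1	producing
HMDB0001999	FADS2	producing
HMDB0002183	ELOVL2	producing
HMDB0002183	FADS2	producing
HMDB0000073	DDC	producing
HMDB0000073	TH	producing
HMDB0000073	MAOA	consuming
HMDB0000259	TPH1	producing
HMDB0000259	DDC	producing
HMDB0000259	MAOA	consuming
HMDB0001341	ENTPD1	producing
HMDB0001341	AK1	consuming
HMDB0000122	G6PC1	producing
HMDB0000122	HK1	consuming
HMDB0000122	HK2	consuming
HMDB0000161	GPT	producing
HMDB0000123	SHMT1	producing
HMDB0000123	SHMT2	producing
HMDB0000123	GLDC	consuming
HMDB0000067	DHCR7	producing
HMDB0000067	CYP27A1	consuming
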