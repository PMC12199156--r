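metabolite_id	sensor_gene	sensor_class	source
HMDB0000641	SLC1A5	transporter	literature
HMDB0000641	SLC38A2	transporter	Recon2
HMDB0000148	GRM1	surface_receptor	literature
HMDB0001999	FFAR4	surface_receptor	literature
HMDB0002183	FFAR4	surface_receptor	literature
HMDB0002183	RXRA	nuclear_receptor	Wikipedia
HMDB0000073	DRD1	surface_receptor	literature
HMDB0000073	SLC6A3	transporter	Recon2
HMDB0000259	HTR1A	surface_receptor	literature
HMDB0000259	SLC6A4	transporter	Recon2
HMDB0001341	P2RY1	surface_receptor	Wikipedia
HMDB0000122	SLC2A1	transporter	Recon2
HMDB0000161	SLC7A8	transporter	Recon2
HMDB0000123	GLRA1	surface_receptor	literature
HMDB0000123	SLC6A9	transporter	Recon2
HMDB0000067	RORA	nuclear_receptor	Wikipedia
HMDB0000067	NR1H3	nuclear_receptor	literature
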