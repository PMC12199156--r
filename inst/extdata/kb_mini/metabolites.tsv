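metabolite_id	name	chem_class	extracellular
HMDB0000641	L-Glutamine	Organic acids and derivatives	TRUE
HMDB0000148	L-Glutamic acid	Organic acids and derivatives	TRUE
HMDB0001999	Eicosapentaenoic acid	Lipids and lipid-like molecules	TRUE
HMDB0002183	Docosahexaenoic acid	Lipids and lipid-like molecules	TRUE
HMDB0000073	Dopamine	Benzenoids	TRUE
HMDB0000259	Serotonin	Organoheterocyclic compounds	TRUE
HMDB0001341	ADP	Nucleosides, nucleotides, and analogues	TRUE
HMDB0000122	D-Glucose	Organic oxygen compounds	TRUE
HMDB0000161	L-Alanine	Organic acids and derivatives	TRUE
HMDB0000123	Glycine	Organic acids and derivatives	TRUE
HMDB0000067	Cholesterol	Lipids and lipid-like molecules	TRUE
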