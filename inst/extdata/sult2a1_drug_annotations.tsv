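effector_gene	protein_type	drugbank_id	drug_name	relation	antagonist	agonist	substrate	inhibitor	inducer
SULT2A1	Enzyme	DB05812	Abiraterone	EnzymeBond	0	0	1	0	0
SULT2A1	Enzyme	DB12471	Ibrexafungerp	EnzymeBond	0	0	1	0	0
SULT2A1	Enzyme	DB00968	Methyldopa	EnzymeBond	0	0	1	0	0
SULT2A1	Enzyme	DB09073	Palbociclib	EnzymeBond	0	0	1	0	0
SULT2A1	Enzyme	DB00960	Pindolol	EnzymeBond	0	0	1	0	0
SULT2A1	Enzyme	DB01708	Prasterone	EnzymeBond	0	0	1	0	0
SULT2A1	Enzyme	DB00675	Tamoxifen	EnzymeBond	0	0	1	0	0
SULT2A1	Enzyme	DB00871	Terbutaline	EnzymeBond	0	0	1	0	0
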