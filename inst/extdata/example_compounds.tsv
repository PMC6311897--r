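id	smiles	label
aspirin	CC(=O)OC1=CC=CC=C1C(=O)O	1
benzoate	OC(=O)C1=CC=CC=C1	1
ethanol	CCO	0
propane	CCC	0
acetamide	CC(=O)N	0
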