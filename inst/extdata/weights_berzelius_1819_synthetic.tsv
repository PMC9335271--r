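chemist	year	element	weight	reference_element
berzelius_1819_synthetic	1819	H	1.008	H
berzelius_1819_synthetic	1819	C	12.011	H
berzelius_1819_synthetic	1819	N	14.007	H
berzelius_1819_synthetic	1819	O	15.999	H
berzelius_1819_synthetic	1819	P	30.974	H
berzelius_1819_synthetic	1819	S	32.06	H
berzelius_1819_synthetic	1819	Cl	35.45	H
berzelius_1819_synthetic	1819	K	39.098	H
berzelius_1819_synthetic	1819	Ca	40.078	H
berzelius_1819_synthetic	1819	Na	22.990	H
berzelius_1819_synthetic	1819	Fe	111.69	H
berzelius_1819_synthetic	1819	Cu	63.546	H
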