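chemist	year	element	weight	reference_element
dalton_1810_synthetic	1810	H	1	H
dalton_1810_synthetic	1810	O	7	H
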