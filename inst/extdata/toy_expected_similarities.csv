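source,target,numerator,denominator
Br,Cl,4,5
Cl,Br,3,5
Na,H,3,3
Na,K,2,3
K,Na,2,2
K,H,2,2
H,Na,3,7
H,K,2,7
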