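id,formula,year
W01,H2O,1800
W02,HCl,1800
W03,NaCl,1807
W04,K2O,1807
W05,Na2O,1807
W06,KCl,1808
W07,HBr,1826
W08,NaBr,1826
W09,C2H2Cl2,1835
W10,C2H2Br2,1840
W11,C2H2Br2,1845
W12,CBr4,1850
W13,CHCl3,1842
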