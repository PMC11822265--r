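strategy,expected_cost,expected_qaly
SCR,31669.62,6.186350
LTTT,28291.50,5.400760
SABS,17103.93,5.535686
RSA,26104.29,4.914692
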