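pattern,acss
AAAAAA,10.85
ABABAB,12.05
BABBAA,15.31
AABBAB,15.02
AAABBB,13.45
ABBABA,15.20
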