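# synthetic example RBP consensus motifs (IUPAC); U is normalized to T on read
rbp1	AAACACAW
rbp2	UGUAHMNUA
rbp3	HWNCAUUWY
rbp4	GGACWW
rbp5	YYAYYYY
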