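gene	sample
TP53	P00001
TP53B	P00001
NCOA3	P00001
IDH1	P00002
NCOA3	P00002
TP53	P00003
TP53B	P00003
BRCA2	P00004
IDH1	P00005
NCOA3	P00006
IDH1	P00007
TP53	P00008
TP53B	P00008
BRCA2	P00009
NCOA3	P00010
NCOA3	P00011
IDH1	P00012
TP53	P00001
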