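gene	P00001	P00002	P00003	P00004	P00005	P00006	P00007	P00008	P00009	P00010	P00011	P00012
TP53	1	0	1	0	0	0	0	1	0	0	0	0
TP53B	1	0	1	0	0	0	0	1	0	0	0	0
IDH1	0	1	0	0	1	0	1	0	0	0	0	1
BRCA2	0	0	0	1	0	0	0	0	1	0	0	0
NCOA3	1	1	0	0	0	1	0	0	0	1	1	0
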