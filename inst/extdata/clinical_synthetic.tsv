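sample_id	time	event	group
P00001	5.08	1	0
P00002	76.61	1	1
P00003	2.1	1	0
P00004	6.13	1	0
P00005	33.8	1	1
P00006	12.76	0	0
P00007	2.93	1	1
P00008	0.33	1	0
P00009	58.11	1	0
P00010	8.21	1	0
P00011	11.27	1	0
P00012	8.41	1	1
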