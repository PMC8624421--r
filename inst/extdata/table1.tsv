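patient	encc_only	blood_only	ppae	ppab	vape	validated
1	50	43	8	11	5	0
2	16	28	2	4	1	0
3	25	33	0	1	0	0
4	96	178	17	11	15	0
5	29	35	2	1	2	0
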