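hybrid	nFM	nFH	nMH	degRatio
AE	10252	2841	6374	65.23
AF	7203	3813	4719	73.14
AG	8643	3141	4098	60.44
AH	9951	3578	5211	62.96
BE	10043	3412	5829	66.45
BF	7053	2349	5136	70.81
BG	8364	2554	3442	54.50
BH	10215	3004	6224	66.90
CE	8078	5990	4424	74.85
CF	6580	5533	3872	72.14
CG	6044	4667	2312	63.78
CH	7880	5095	7036	76.79
DE	9064	3009	6376	68.53
DF	5815	1796	2244	51.93
DG	7853	3313	2822	55.52
DH	7462	3495	3550	64.84
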