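# VTE susceptibility SNP panel: 38 variants in 26 genes.
# Columns beyond the five core fields carry the published cohort effect-allele
# frequencies (cases n=122, controls n=87) used by the synthetic generator.
# effect_allele "-" denotes a deletion allele (rs8176719 is an indel).
gene	rsid	effect_allele	reference_allele	literature_or	category	eaf_case	eaf_control
PROC	rs146922325	T	C	6.91	established	0.16	0.09
THBD	rs16984852	A	C	2.80	established	0.01	0.00
F2	rs1799963	A	G	1.88	established	0.00	0.00
F2	rs191945074	T	C	1.86	established	0.09	0.08
ABO	rs8176719	C	-	1.85	established	0.46	0.40
ABO	rs8176743	T	C	1.76	established	0.26	0.17
FGG	rs2066865	A	G	1.56	established	0.52	0.36
PAI-1	rs2227631	A	G	1.55	established	0.42	0.42
APOH	rs8178847	T	C	1.55	established	0.02	0.05
NOS3	rs1799983	T	G	1.41	established	0.14	0.14
ABO	rs2519093	T	C	1.40	established	0.24	0.21
ABO	rs9411377	A	C	1.36	established	0.00	0.00
ABO	rs687289	A	G	1.34	established	0.63	0.55
F11	rs2036914	T	C	1.32	established	0.19	0.24
MTHFR	rs1801133	T	C	1.30	established	0.09	0.11
F11	rs2289252	T	C	1.26	established	0.55	0.48
ABO	rs8176749	T	C	1.23	established	0.24	0.18
F11	rs4253417	C	T	1.22	established	0.54	0.43
SERPINC1	rs2227589	T	C	1.20	established	0.33	0.37
HIVEP1	rs169713	C	T	1.20	established	0.28	0.19
TSPAN15	rs78707713	T	C	1.20	established	0.97	0.95
FGG	rs2066864	A	G	1.20	established	0.80	0.74
KNG1	rs710446	G	A	1.19	established	0.36	0.39
F2	rs3136516	G	A	1.19	established	0.86	0.82
PROS1	rs6795524	G	A	1.19	established	0.04	0.03
CYP4V2	rs13146272	A	C	1.17	established	0.54	0.56
VWF	rs1063856	C	T	1.16	established	0.07	0.08
GP6	rs1613662	G	A	1.15	established	0.09	0.07
F5	rs4524	C	T	0.88	established	0.09	0.22
SERPINC1	rs2227624	A	T	0.99	novel	0.00	0.00
PDIA3	rs139974673	T	C	0.98	novel	1.00	1.00
PPP1R3B	rs34290760	C	G	0.96	novel	0.99	0.99
SYK	rs10993706	A	G	0.93	novel	0.23	0.17
TGFB2	rs57615042	A	G	0.89	novel	0.69	0.78
MTOR	rs12097293	A	G	0.77	novel	0.93	0.91
KNG1	rs5030062	A	C	0.63	novel	0.63	0.61
ZFPM1	rs55823018	T	C	0.31	novel	0.58	0.57
XXYLT1	rs56324901	A	G	0.20	novel	0.45	0.48
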