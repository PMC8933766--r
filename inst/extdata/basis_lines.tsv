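metabolite	ppm	amplitude	hwhm_ppm
NAA	2.008	3.0	0.02
NAA	2.49	0.8	0.02
NAA	2.67	0.8	0.02
NAAG	2.042	3.0	0.02
NAAG	2.52	0.6	0.02
Cr	3.027	3.0	0.02
Cr	3.913	2.0	0.02
PCr	3.047	3.0	0.02
PCr	3.935	2.0	0.02
Glu	2.04	1.0	0.02
Glu	2.12	1.0	0.02
Glu	2.35	1.5	0.02
Glu	3.75	1.0	0.02
Gln	2.135	1.0	0.02
Gln	2.45	1.5	0.02
Gln	3.77	1.0	0.02
Ins	3.52	2.0	0.02
Ins	3.61	1.5	0.02
Ins	4.06	1.0	0.02
Tau	3.25	2.0	0.02
Tau	3.42	2.0	0.02
Cho	3.185	3.0	0.02
Cho	4.05	0.5	0.02
PCh	3.205	3.0	0.02
PCh	3.58	0.5	0.02
GPC	3.228	3.0	0.02
GPC	3.66	0.5	0.02
GPC	3.90	0.3	0.02
GSH	2.15	0.6	0.02
GSH	2.55	0.8	0.02
GSH	2.95	1.5	0.02
GSH	3.78	0.8	0.02
GABA	1.89	1.5	0.02
GABA	2.28	1.5	0.02
GABA	3.01	1.5	0.02
Lac	1.31	3.0	0.02
Lac	4.10	1.0	0.02
MM	0.91	2.0	0.08
MM	1.21	2.0	0.08
MM	1.43	1.5	0.08
MM	2.05	1.0	0.08
MM	3.00	0.8	0.08
Lip	0.90	3.0	0.07
Lip	1.30	4.0	0.07
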