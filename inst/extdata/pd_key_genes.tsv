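gene	fc_all_p01	fc_male_p01	fc_male_p05	fc_female_p01	fc_female_p05
TNFRSF1A	0	0	0	1.25	1.26
PINK1	-2.08	-1.85	-1.82	0	-2.55
SOD1	-3.44	-3.44	-3.44	0	0
PARK7	-7.14	-9.09	-8.37	0	0
NDUFA6	-1.80	0	-2.19	-1.56	-2.07
NDUFB8	-7.14	-5.55	-3.00	0	-10.96
CYP1A1	1.2	0	0	1.36	1.36
CYP2C9	0	1.23	1.23	0	0
APAF1	1.35	1.41	1.40	0	0
GSTA4	-1.38	-1.38	-1.38	0	0
SNCA	-1.88	-2.12	-1.12	0	-1.84
PSMA7	-1.72	0	0	-1.78	-1.77
HSP90AA1	-2.70	-3.33	-3.46	0	0
HSPA8	-2.77	-3.70	-1.35	0	0
LAMP1	0	0	0	-12.50	-11.50
PPARD	0	1.20	1.20	0	0
DRD1	0	0	0	1.37	1.37
DRD2	1.26	1.32	1.32	1.32	1.32
CHRNA4	1.25	1.22	1.22	1.4	1.40
GABARAPL2	-1.53	-1.51	-1.50	0	-1.54
GRIN2B	1.27	1.27	1.27	0	1.25
TGFB2	1.24	0	1.24	1.33	1.33
KCNN3	0	0	0	-1.92	-1.91
SLC24A3	0	-1.56	-1.55	0	0
SLC6A4	0	0	0	1.33	1.33
CCK	-1.23	-1.31	-1.30	0	0
CCKAR	1.31	1.31	1.31	0	0
VDR	1.39	1.39	1.39	0	1.31
FYN	-1.19	-1.19	-1.19	0	-1.92
RIPK2	1.29	0	0	1.29	1.29
MAPT	-5	0	0	-5	-4.9
FTH1	-2.81	-2.77	-2.74	0	0
FTL	-1.88	-1.81	-1.80	0	0
PPP1R3A	1.25	1.24	1.24	0	0
PPP3CA	-2.56	-3.03	-2.94	0	0
ST13	-1.67	0	0	-1.64	-1.67
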