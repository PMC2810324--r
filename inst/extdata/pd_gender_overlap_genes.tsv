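gene	allN_allPD	fN_fPD	mN_mPD	mN_fN	mPD_fPD
ATP5G3	-2.25	-2.17	-2.94	0	0
ATP6V1E1	-3.57	-4.76	-3.23	0	0
CHRNA4	1.25	1.4	1.22	0	0
CLTC	-1.33	-5.56	-3.12	0	0
COX7C	-2.90	-2.56	-3.64	0	0
DRD2	1.26	1.33	1.32	0	0
NDUFB2	-3.39	-2.22	-3.70	0	0
PRKACB	-2.44	1.35	-2.70	0	0
SLC35A1	-1.49	-1.79	-1.37	0	0
SLC6A1	-1.67	-1.85	-1.56	0	0
TIMM44	0	-1.49	1.26	0	0
UQCRH	-2.94	-3.45	-2.63	0	0
ZNF606	1.31	1.4	1.27	0	0
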