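gene	dn	trans	nontrans	case	control	p_dn	p_tada_lof
KATNAL2	2	1	0	4	0	3.1e-6	2e-7
CHD8	2	0	0	3	0	9.5e-5	2.4e-6
LMCD1	0	2	0	0	0	1	0.067
S100G	1	0	0	3	0	0.00042	1.6e-5
DYRK1A	2	0	0	0	0	8.6e-6	4.3e-6
PPM1D	1	0	0	2	0	0.0032	0.00023
SCN2A	2	0	0	0	0	5.9e-5	2.8e-5
CUL3	1	0	0	3	0	0.004	0.00013
DEAF1	0	2	0	1	0	1	0.031
BANK1	0	1	0	4	0	1	0.0064
POGZ	2	0	0	0	0	3e-5	1.4e-5
WDR55	0	1	0	0	0	1	0.18
FAM91A1	1	0	0	0	0	0.0046	0.0019
COL25A1	1	0	0	5	0	0.0034	2.3e-5
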