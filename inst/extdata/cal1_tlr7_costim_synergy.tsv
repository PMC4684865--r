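gene_symbol	unigene_id	fc_a	fc_b	fc_combo	reported_ratio
CD69	Hs.208854	2.4	6.1	64.2	7.6
BCL2A1	Hs.227817	2.7	22.2	96.6	3.9
BIRC3	Hs.127799	1.2	6.4	25.6	3.4
REPS2	Hs.186810	1.0	2.4	10.3	3.1
IFNB1	Hs.93177	1.6	1.9	10.8	3.1
ST20	Hs.729127	1.3	4.8	18.5	3.0
CCL2	Hs.303649	0.6	41.4	126.0	3.0
CD44	Hs.502328	1.5	4.3	17.5	3.0
EGR3	Hs.534313	2.1	3.3	15.9	2.9
TTLL2	Hs.520554	1.1	3.1	11.9	2.8
OBFC2A	Hs.591610	1.7	12.4	38.6	2.7
IL-6	Hs.654458	0.9	4.9	14.7	2.6
NFKBIA	Hs.81328	1.6	6.2	19.6	2.5
MIR155HG	NA	1.5	1.9	8.1	2.4
CCL1	Hs.72918	2.4	15.6	41.8	2.3
RASGEF1B	Hs.591696	1.1	3.3	10.2	2.3
CD70	Hs.501497	1.4	6.1	16.5	2.2
GPR183	Hs.784	1.0	2.6	7.8	2.2
ADAMTS10	Hs.657508	1.0	1.9	6.1	2.1
ADAM19	Hs.483944	2.4	3.6	12.6	2.1
FRG2C	Hs.274541	0.8	1.1	4.1	2.1
IL-23A	Hs.98309	1.6	7.8	19.4	2.1
EFCAB3	Hs.152670	1.0	1.3	4.8	2.1
NCF2	Hs.587558	1.8	3.8	11.5	2.1
IL-1B	Hs.126256	1.0	7.3	17.0	2.1
NR4A3	Hs.279522	1.4	3.1	9.4	2.1
TNFAIP3	Hs.211600	1.5	3.5	10.2	2.1
RGS1	Hs.75256	1.7	3.5	10.7	2.0
SGK1	Hs.510078	0.5	1.8	4.8	2.0
REL	Hs.631886	1.1	2.4	6.7	2.0
IER3	Hs.76095	0.8	4.3	9.9	1.9
NFKBIZ	Hs.319171	1.3	2.7	7.8	1.9
CCL4L2	Hs.661942	2.0	21.0	43.9	1.9
IL-18R1	Hs.469521	2.5	6.9	17.9	1.9
IL-8	Hs.624	1.8	2.4	7.9	1.9
CFLAR	Hs.390736	1.5	2.2	6.8	1.9
PIM2	Hs.496096	0.8	3.0	7.1	1.8
SAT1	Hs.28491	1.6	3.6	9.5	1.8
IL-4I1	Hs.574492	1.2	4.0	9.4	1.8
CXCL10	Hs.632586	1.6	5.8	13.1	1.8
SLC29A2	Hs.569017	1.4	3.4	8.6	1.8
LINC00173	NA	1.8	3.2	8.8	1.8
MAP3K8	Hs.432453	1.1	4.1	9.1	1.8
STAT5A	Hs.437058	0.8	1.9	4.6	1.7
ARL5B	Hs.25362	1.5	3.1	7.9	1.7
NINJ1	Hs.494457	0.9	3.4	7.3	1.7
WNT10A	Hs.121540	1.2	5.8	11.6	1.6
BTG1	Hs.255935	1.5	2.6	6.7	1.6
FSCN1	Hs.118400	0.5	1.6	3.5	1.6
CD83	Hs.595133	1.7	5.2	11.4	1.6
PDGFA	Hs.535898	1.4	2.3	6.1	1.6
TFEC	Hs.125962	0.6	3.1	6.1	1.6
CD40	Hs.472860	1.0	4.1	8.4	1.6
POU2F2	Hs.654420	0.6	3.2	6.2	1.6
NCOA7	Hs.171426	1.6	2.7	6.8	1.6
ZFP36L1	Hs.85155	1.3	2.0	5.1	1.6
SLC7A11	Hs.390594	1.4	2.2	5.7	1.6
FRG2	Hs.626907	1.1	1.3	3.7	1.5
hsa-mir-146a	NA	1.1	3.7	7.3	1.5
hsa-mir-21	NA	1.6	1.7	5.1	1.5
BTBD19	Hs.632400	0.8	1.7	3.9	1.5
ELOVL6	Hs.412939	1.1	1.7	4.2	1.5
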