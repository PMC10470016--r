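pathway_id	pathway_name	del_count	del_ratio	dem_count	dem_ratio
ko04624	Toll/Imd signaling pathway	44	0.00515283	117	0.00882153
ko04620	Toll-like receptor signaling pathway	33	0.00386462	80	0.00603182
ko04621	NOD-like receptor signaling pathway	47	0.00550416	120	0.00904773
ko04622	RIG-I-like receptor signaling pathway	34	0.00398173	78	0.00588102
ko04630	JAK/STAT signaling pathway	32	0.00374751	63	0.00475006
ko04064	NF-kB signaling pathway	40	0.00468439	107	0.00806756
ko04151	PI3K-Akt signaling pathway	89	0.01042277	223	0.01681369
ko04657	IL-17 signaling pathway	22	0.00257641	49	0.00369449
ko04010	MAPK signaling pathway - fly	91	0.01065699	232	0.01749227
ko04142	Lysosome	88	0.01030566	286	0.02156375
ko04668	TNF signaling pathway	41	0.0048015	84	0.00633341
ko04625	C-type lectin receptor signaling pathway	48	0.00562127	98	0.00738898
ko04350	TGF-beta signaling pathway	42	0.00491861	90	0.0067858
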