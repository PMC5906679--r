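name	trait	chrom	start	end	source
qFe6	Fe	6	16404065	21506253	linkage
qFe7	Fe	7	27770508	27788464	linkage
qZn7	Zn	7	22891126	26101517	linkage
qZn12	Zn	12	21887797	21913241	linkage
qCd1	Cd	1	212589	1905348	linkage
qCd4	Cd	4	26418529	30460722	linkage
qCd6	Cd	6	10411282	11457254	linkage
qCd8	Cd	8	98858	736546	linkage
qCd11	Cd	11	6233769	6354200	linkage
id1005056-58 (Norton2014)	Zn	1	6179574	6204400	literature
qZn7 (Huang2015)	Zn	7	22891126	26101517	literature
qZn7 (Hu2016)	Zn	7	22891126	26101517	literature
qZN-7 (Lu2008)	Zn	7	22891126	26101517	literature
id7003641 (Norton2014)	Zn	7	22891126	26101517	literature
qCd2b (Zhang2014)	Cd	2	25207241	33640277	literature
qCd3 (Zhang2014)	Cd	3	1652156	2158456	literature
qCd3 (Huang2015)	Cd	3	32638170	35155759	literature
qCd4-2 (Kashiwagi2009)	Cd	4	26418529	30460722	literature
qCd5 (Zhang2014)	Cd	5	1142167	3242916	literature
qCd5.1 (Huang2015)	Cd	5	16818124	19141063	literature
Segment_on_Chr6 (Ishikawa2010)	Cd	6	10411282	11457254	literature
OsLCT1 (Uraguchi2011)	Cd	6	22117058	22123339	literature
qCd6 (Zhang2014)	Cd	6	28441362	29887070	literature
qGCd7/qSCd7 (Ishikawa2012)	Cd	7	9491735	10356836	literature
qCdp7 (Abe2013)	Cd	7	9491735	10356836	literature
qCDCN-7 (Shen2008)	Cd	7	17677268	24927574	literature
Segment_on_Chr8 (Ishikawa2010)	Cd	8	98858	736546	literature
qCd8 (Zhang2014)	Cd	8	24758957	26561629	literature
qCd11 (Kashiwagi2010)	Cd	11	16915560	20181453	literature
qCd11 (Tang2007)	Cd	11	23757657	27669556	literature
qSCd12 (Ishikawa2012)	Cd	12	24218754	25662740	literature
qCu5 (Zhang2014)	Cu	5	3343234	3704085	literature
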