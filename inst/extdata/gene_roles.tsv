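gene	role	chrom	start	end	source
WT1	recessive	chr11	32400000	32460000	census
TP53	recessive	chr17	7565097	7590856	census
TRIM28	recessive	chr19	59055000	59062000	wilms
CTNNB1	oncogene	chr3	41236328	41301587	census
MYCN	oncogene	chr2	16080000	16087100	census
PIK3CA	oncogene	chr3	178866311	178952497	census
AMER1	recessive	chrX	63404000	63425000	wilms
CHEK2	recessive	chr22	29083731	29137822	census
FBXW7	recessive	chr4	153242410	153456185	census
IGF2	oncogene	chr11	2150342	2170833	wilms
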