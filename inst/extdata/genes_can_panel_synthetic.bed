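chr11	20000000	20100000	CD248
chr10	20000000	20100000	ERCC6
chr20	20000000	20100000	ERGIC3
chr20	21000000	21100000	GNAS
chr16	20000000	20100000	MMP2
chr17	20000000	20100000	NF1
chr12	20000000	20100000	P2RX7
chr20	22000000	22100000	SFRS6
chr6	20000000	20100000	SLC29A1
chrX	20000000	20100000	TBX22
chr4	20000000	20100000	ADAM29
chr3	20000000	20100000	CHL1
chr8	20000000	20100000	CSMD3
chr4	21000000	21100000	FBXW7
chr16	21000000	21100000	GALNS
chr14	20000000	20100000	PRKD1
chr18	20000000	20100000	SMAD4
chr17	21000000	21100000	TP53
chr18	21000000	21100000	SMAD2
chr3	21000000	21100000	TGFBR2
chr12	21000000	21100000	KRAS
chr6	21000000	21100000	HIST1H1B
chr3	22000000	22100000	P2RY14
chr6	22000000	22100000	PHIP
chr8	21000000	21100000	RUNX1T1
chr13	20000000	20100000	LMO7
chr6	23000000	23100000	SYNE1
chr9	20000000	20100000	PTPRD
chr1	20000000	20100000	LGR6
chr10	21000000	21100000	RET
chr14	21000000	21100000	EVL
chr6	24000000	24100000	CD109
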