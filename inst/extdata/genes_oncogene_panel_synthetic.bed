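chr3	10000000	10100000	RAF1
chr8	11000000	11100000	E2F5
chr8	12000000	12100000	EXT1
chr11	10000000	10100000	LRRC32
chr11	11000000	11100000	ATM
chr11	12000000	12100000	INS
chr18	10000000	10100000	DCC
chrX	10000000	10100000	KAL1
chr20	10000000	10100000	GNAS
chr20	11000000	11100000	AURKA
chr20	12000000	12100000	SRC
chr20	13000000	13100000	TOP1
chr17	10000000	10100000	TP53
chr18	11000000	11100000	SMAD4
chr12	10000000	10100000	KRAS
chr5	10000000	10100000	APC
chr8	13000000	13100000	MYC
chr11	13000000	13100000	CCND1
chr7	10000000	10100000	EGFR
chr17	11000000	11100000	ERBB2
chr10	10000000	10100000	PTEN
chr13	10000000	10100000	RB1
chr3	11000000	11100000	MLH1
chr2	10000000	10100000	MSH2
chr7	11000000	11100000	BRAF
chr3	12000000	12100000	PIK3CA
chr3	13000000	13100000	CTNNB1
chr4	10000000	10100000	FBXW7
chr9	10000000	10100000	CDKN2A
chr13	11000000	11100000	CDX2
chr18	12000000	12100000	BCL2
chr1	10000000	10100000	NRAS
chr7	12000000	12100000	MET
chr6	10000000	10100000	VEGFA
chr18	13000000	13100000	TYMS
chr5	11000000	11100000	TERT
chr12	11000000	11100000	MDM2
chr12	12000000	12100000	CDK4
chr6	11000000	11100000	ESR1
chr14	10000000	10100000	AKT1
chr9	11000000	11100000	NOTCH1
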