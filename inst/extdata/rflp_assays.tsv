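# PCR-RFLP assays distinguishing sequence-family variants of the multicopy
# DAZ, GOLY, BPY2 and TTTY4 genes. fragments_A/B: published fragment
# patterns of the undigested (A) and digested (B) alleles, '+'-separated.
# cut_top: bases of the recognition pattern preceding the top-strand cut.
target	snv	amplicon_bp	enzyme	recognition	cut_top	fragments_A	fragments_B
DAZ	DAZ-SNV_I	709	FspI	TGCGCA	3	709	398+311
DAZ	DAZ-SNV_II	182	MboI	GATC	0	182	122+60
DAZ	DAZ-SNV_III	301	TaqI	TCGA	1	301	184+117
DAZ	DAZ-SNV_IV	630	AluI	AGCT	2	630	398+262
DAZ	DAZ-SNV_V	244	DraI	TTTAAA	3	195+49	122+73+49
DAZ	DAZ-SNV_VI	431	AflIII	ACRYGT	1	431	248+183
DAZ	DAZ-SNV_VII	252	Sau3AI	GATC	0	189+63	130+63+59
GOLY	GOLY-SNV_1	531	HhaI	GCGC	3	531	289+282
BPY2	BPY2	470	EcoRV	GATATC	3	470	289+181
TTTY4	TTTY4	541	HaeIII	GGCC	2	541	323+218
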