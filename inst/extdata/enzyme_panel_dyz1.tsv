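# 65-enzyme panel for virtual restriction mapping of the 3.56 kb DYZ1 unit.
# overhang: blunt | 5p | 3p. cut_top/cut_bottom: bases of (or beyond) the
# recognition pattern preceding the top/bottom-strand cut, from the pattern
# start on the strand carrying it; NA = offset not curated (site counting
# only, no fragmentation).
name	recognition	overhang	cut_top	cut_bottom
BsaBI	GATNNNNATC	blunt	5	5
Cac8I	GCNNGC	blunt	3	3
NlaIV	GGNNCC	blunt	3	3
BamHI	GGATCC	5p	1	5
BseYI	CCCAGC	5p	1	5
Bsp1407I	TGTACA	5p	1	5
BspHI	TCATGA	5p	1	5
ClaI	ATCGAT	5p	2	4
DdeI	CTNAG	5p	1	4
EcoRI	GAATTC	5p	1	5
EcoRII	CCWGG	5p	0	5
MaeII	ACGT	5p	1	3
MaeIII	GTNAC	5p	0	5
VspI	ATTAAT	5p	2	4
XhoII	RGATCY	5p	1	5
BseMII	CTCAG	3p	15	13
BsgI	GTGCAG	3p	22	20
BtsI	GCAGTG	3p	8	6
Eco57I	CTGAAG	3p	22	20
Eco57MI	CTGRAG	3p	22	20
GsuI	CTGGAG	3p	22	20
Hpy188I	TCNGA	3p	3	2
MnlI	CCTC	3p	11	10
PflMI	CCANNNNNTGG	3p	7	4
SduI	GDGCHC	3p	5	1
ScrFI	CCNGG	5p	2	3
ArsI	GACNNNNNNTTYG	3p	NA	NA
BdaI	TGANNNNNNTCA	3p	NA	NA
CspCI	CAANNNNNGTGG	3p	NA	NA
TspRI	CASTG	3p	NA	NA
DpnI	GATC	blunt	2	2
ApoI	RAATTY	5p	1	5
AsuII	TTCGAA	5p	2	4
Eco31I	GGTCTC	5p	7	11
MaeI	CTAG	5p	1	3
MboI	GATC	5p	0	4
SfaNI	GCATC	5p	10	14
TatI	WGTACW	5p	1	5
SetI	ASST	3p	NA	NA
CviJI	RGCY	blunt	2	2
MslI	CAYNNNNRTG	blunt	5	5
FokI	GGATG	5p	14	18
AlfI	GCANNNNNNTGC	3p	NA	NA
RsaI	GTAC	blunt	2	2
BccI	CCATC	5p	9	10
BsmAI	GTCTC	5p	6	10
MseI	TTAA	5p	1	3
BstXI	CCANNNNNNTGG	3p	8	4
MboII	GAAGA	3p	13	12
XmnI	GAANNNNTTC	blunt	5	5
TstI	CACNNNNNNTCC	3p	NA	NA
NlaIII	CATG	3p	4	0
BcgI	CGANNNNNNTGC	3p	NA	NA
BsrDI	GCAATG	3p	8	6
BsrI	ACTGG	3p	6	4
TspGWI	ACGGA	3p	16	14
AgsI	TTSAA	3p	NA	NA
BsmI	GAATGC	3p	7	5
FaiI	YATR	blunt	2	2
PleI	GAGTC	5p	9	10
TspDTI	ATGAA	3p	16	14
TspEI	AATT	5p	0	4
TfiI	GAWTC	5p	1	4
TaqI	TCGA	5p	1	3
HinfI	GANTC	5p	1	4
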