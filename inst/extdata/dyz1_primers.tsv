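# Primers tiling the 3.56 kb DYZ1 array. Locations are 1-based inclusive
# on the array; SAS 1 anneals upstream of the HaeIII site and has no
# in-array coordinates. orientation: forward | reverse.
id	seq	length	start	end	orientation	note
SAS1	CCATTCGAGACCGTAGCAAT	20	NA	NA	forward	anneals 35-16 bp upstream of the HaeIII site
SAS2	TTTCCTTTCGCTTGCATTCCAT	22	63	84	forward
SAS3	ATTTGATGCCATCCCATGAC	20	763	782	forward
SAS4	TTTTGAGTCCGTTCCATAACAC	22	1380	1401	forward
SAS5	TCCTTTGCCTTCCATTCG	18	1668	1685	forward
SAS6	TGCAGTCTTTTCCCTTCGAG	20	2564	2583	forward
SAS7	ATTGGATGGGATTGGAATGA	20	861	880	reverse
SAS8	TGGATGGACTGCAATAGAAAG	22	1600	1621	reverse
SAS9	TCGAATGGAAGGCAAAGG	18	1669	1686	reverse
SAS10	CGACTGGTACGGACTCCAAT	20	2637	2656	reverse
SAS11	GACTGGAAAGGCTGGGTGTCGA	22	3419	3440	reverse
SAS12	TGGACAGCCTGGAATAAAGTG	21	3551	3571	reverse	printed location 3586-3606 is in clone coordinates (35 bp upstream flank included); converted to the array frame
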