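# The 19 DYZ1 primer combinations used for end-point PCR intactness
# checks, with published amplicon sizes. conditions (annealing/extension)
# are inert metadata.
combination	fwd_id	rev_id	amplicon_bp	conditions
SAS(1&7)	SAS1	SAS7	915	64C-1.0', 72C-1.0'
SAS(1&8)	SAS1	SAS8	1656	65C-1.0', 72C-2.0'
SAS(1&9)	SAS1	SAS9	1721	61C-1.0', 72C-2.0'
SAS(2&7)	SAS2	SAS7	818	61C-1.0', 72C-1.0'
SAS(2&8)	SAS2	SAS8	1559	60C-1.0', 72C-1.5'
SAS(3&7)	SAS3	SAS7	118	55C-1.0', 72C-1.0'
SAS(3&8)	SAS3	SAS8	859	65C-1.0', 72C-1.0'
SAS(3&9)	SAS3	SAS9	924	61C-1.0', 72C-1.0'
SAS(3&10)	SAS3	SAS10	1894	64C-1.0', 72C-2.0'
SAS(4&8)	SAS4	SAS8	242	61C-1.0', 72C-1.0'
SAS(4&9)	SAS4	SAS9	307	55C-1.0', 72C-1.0'
SAS(4&10)	SAS4	SAS10	1277	61C-1.0', 72C-1.5'
SAS(4&11)	SAS4	SAS11	2061	62C-1.0', 72C-2.5'
SAS(4&12)	SAS4	SAS12	2192	61C-1.0', 72C-2.5'
SAS(5&10)	SAS5	SAS10	989	61C-1.0', 72C-1.0'
SAS(5&12)	SAS5	SAS12	1904	61C-1.0', 72C-2.0'
SAS(6&10)	SAS6	SAS10	93	61C-1.0', 72C-1.0'
SAS(6&11)	SAS6	SAS11	877	61C-1.0', 72C-1.0'
SAS(6&12)	SAS6	SAS12	1008	64C-1.0', 72C-1.0'
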