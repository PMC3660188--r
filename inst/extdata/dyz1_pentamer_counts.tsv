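# Published occurrence of the TTCCA pentamer and its derivative classes per
# DYZ1 HaeIII unit: reference (GenBank AC068123.5), DU145 and LNCaP.
# kind: size (unit length, bp) | motif (single pentamer) | aggregate
# (total over a Hamming-distance class).
row	kind	distance	AC068123.5	DU145	LNCaP
actual_size_bp	size	NA	3564	3564	3465
TTCCA	motif	0	229	235	228
1_bp_derivatives	aggregate	1	292	289	282
ATCCA	motif	1	11	9	9
TACCA	motif	1	3	3	2
TTACA	motif	1	14	13	15
TTCAA	motif	1	21	22	22
TTTCA	motif	1	19	19	19
TTCTA	motif	1	25	25	25
TTCCT	motif	1	32	33	33
GTCCA	motif	1	27	31	28
TGCCA	motif	1	9	10	10
TTGCA	motif	1	25	22	22
TTCGA	motif	1	60	60	57
TTCCG	motif	1	18	17	16
CTCCA	motif	1	14	14	14
TCCCA	motif	1	6	4	4
TTCCC	motif	1	8	7	6
2_bp_derivatives	aggregate	2	142	142	139
3_bp_derivatives	aggregate	3	37	33	30
4_bp_derivatives	aggregate	4	9	9	10
5_bp_derivatives	aggregate	5	1	1	1
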