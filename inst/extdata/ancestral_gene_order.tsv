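# Ancestral arthropod mitochondrial gene arrangement (the Limulus polyphemus /
# Drosophila yakuba ground pattern), linearized to start at COX1 on the major
# strand. This is the widely published ancestral arrangement used as the
# reference template for rearrangement analysis and for the synthetic genome
# generator. Curated by hand from the standard arthropod gene map.
# typical_length is a representative gene length in bases (PCG lengths are
# multiples of 3 and include start and stop codons).
# Columns: position, label, cls, strand, typical_length
position	label	cls	strand	typical_length
1	COX1	PCG	+	1536
2	trnL2	tRNA	+	66
3	COX2	PCG	+	684
4	trnK	tRNA	+	70
5	trnD	tRNA	+	66
6	ATP8	PCG	+	159
7	ATP6	PCG	+	678
8	COX3	PCG	+	786
9	trnG	tRNA	+	65
10	ND3	PCG	+	351
11	trnA	tRNA	+	65
12	trnR	tRNA	+	65
13	trnN	tRNA	+	65
14	trnS1	tRNA	+	66
15	trnE	tRNA	+	66
16	trnF	tRNA	-	66
17	ND5	PCG	-	1611
18	trnH	tRNA	-	65
19	ND4	PCG	-	1338
20	ND4L	PCG	-	291
21	trnT	tRNA	+	65
22	trnP	tRNA	-	66
23	ND6	PCG	+	522
24	CYTB	PCG	+	1137
25	trnS2	tRNA	+	66
26	ND1	PCG	-	936
27	trnL1	tRNA	-	65
28	rrnL	rRNA	-	1160
29	trnV	tRNA	-	72
30	rrnS	rRNA	-	720
31	trnI	tRNA	+	65
32	trnQ	tRNA	-	69
33	trnM	tRNA	+	69
34	ND2	PCG	+	1020
35	trnW	tRNA	+	66
36	trnC	tRNA	-	66
37	trnY	tRNA	-	66
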