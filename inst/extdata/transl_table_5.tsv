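# NCBI genetic code transl_table 5 (invertebrate mitochondrial).
# Differences from the standard code: AGA/AGG -> Ser, ATA -> Met, TGA -> Trp;
# stop codons TAA and TAG. 62 sense codons + 2 stops.
# Columns: codon (DNA alphabet), aa (one-letter), is_stop (0/1).
codon	aa	is_stop
AAA	K	0
AAC	N	0
AAG	K	0
AAT	N	0
ACA	T	0
ACC	T	0
ACG	T	0
ACT	T	0
AGA	S	0
AGC	S	0
AGG	S	0
AGT	S	0
ATA	M	0
ATC	I	0
ATG	M	0
ATT	I	0
CAA	Q	0
CAC	H	0
CAG	Q	0
CAT	H	0
CCA	P	0
CCC	P	0
CCG	P	0
CCT	P	0
CGA	R	0
CGC	R	0
CGG	R	0
CGT	R	0
CTA	L	0
CTC	L	0
CTG	L	0
CTT	L	0
GAA	E	0
GAC	D	0
GAG	E	0
GAT	D	0
GCA	A	0
GCC	A	0
GCG	A	0
GCT	A	0
GGA	G	0
GGC	G	0
GGG	G	0
GGT	G	0
GTA	V	0
GTC	V	0
GTG	V	0
GTT	V	0
TAA	*	1
TAC	Y	0
TAG	*	1
TAT	Y	0
TCA	S	0
TCC	S	0
TCG	S	0
TCT	S	0
TGA	W	0
TGC	C	0
TGG	W	0
TGT	C	0
TTA	L	0
TTC	F	0
TTG	L	0
TTT	F	0
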