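# rgp-scheme	version=1
# Typing scheme for the S. thermophilus rgp locus.
# record=pair: name/panel/forward/reverse/amplicon(bp)/targets(Rgp groups)/type_label
#   panel is one of classification, control, multiplex1, multiplex2; the
#   "control" pair (MSControl) is shared by both multiplex panels; RGPpos is
#   the positive control of the classification panel. type_label is the
#   variable type (Vt*) for multiplex1 pairs, the backbone type (Bt*) for
#   multiplex2 pairs, and the legacy Rgp group for classification pairs.
# record=binomial: name is the V x B binomial, targets is the Rgp group.
# Primer sequences are written 5'->3'.
record	name	panel	forward	reverse	amplicon	targets	type_label
pair	RGPpos	classification	CAGGTGCAAATGGCCAACTCG	CTTGCCATGTTGGGATGAC	801	all	.
pair	RGPgroup1	classification	GGATGATGGTTCGACGGATAG	CCGCTCTTCCAAAACCATGA	631	1	1
pair	RGPgroup2	classification	GTGAAGAGTCAGAAGACGAAT	CAAAGGCCCCGATGGTATT	464	2	2
pair	RGPgroup3	classification	GAGGAAGCAACAGATAAACGA	GACCAATTGGTCCACAAAAGT	303	3	3
pair	RGPgroup4	classification	CTCCTCGTACTCACCCAC	GCACAAGATACAGCTCGTTAC	162	4	4
pair	MSControl	control	GCTGGTCGTAATTACCTCG	CAACATCTTCCAAGGTACG	2724	all	.
pair	Var1	multiplex1	GTATATAATGCACAAGAGGG	GAAACTAATCTTAAGCGTTCC	895	1,2	Vt1
pair	Var2	multiplex1	GGAACCATTGAAGTAAGG	CTTTCAGACCTAACATTTGAC	546	2A	Vt2
pair	Var3	multiplex1	GCTTCCAGATGCAAAAACG	GTGTTACTATCATGGCAAG	271	3,4	Vt3
pair	Var4	multiplex1	GTGAAGAATGTAGATGACC	CAATAACAAGTGCTAAGAC	1086	6	Vt4
pair	Var5	multiplex1	CCCCATTGGAGGATATACGCAG	TGGGTAGTACGGTTCGTCAC	376	7	Vt5
pair	Fg1	multiplex2	GTCATGTGCTCTACCAATTG	GATGGAGCTTATAACGTTC	1481	1,6,7	Bt1
pair	Fg2	multiplex2	GTCTTTCATACCATCCATG	GTTCAACTGCTTATTATCG	1040	2,2A,3	Bt2
pair	Fg3	multiplex2	GCTTGGCATGATGGTATG	GAATAACATCACGTCCTCG	852	4,5	Bt3
binomial	V1B1	.	.	.	.	1	.
binomial	V1B2	.	.	.	.	2	.
binomial	V2B2	.	.	.	.	2A	.
binomial	V3B2	.	.	.	.	3	.
binomial	V3B3	.	.	.	.	4	.
binomial	V4B1	.	.	.	.	6	.
binomial	V5B1	.	.	.	.	7	.
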