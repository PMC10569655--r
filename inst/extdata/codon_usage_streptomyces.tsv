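aa	codon	freq
A	GCC	0.45
A	GCG	0.33
A	GCA	0.12
A	GCT	0.10
R	CGC	0.41
R	CGG	0.32
R	CGT	0.12
R	CGA	0.07
R	AGG	0.05
R	AGA	0.03
N	AAC	0.88
N	AAT	0.12
D	GAC	0.89
D	GAT	0.11
C	TGC	0.85
C	TGT	0.15
Q	CAG	0.92
Q	CAA	0.08
E	GAG	0.78
E	GAA	0.22
G	GGC	0.55
G	GGG	0.22
G	GGT	0.15
G	GGA	0.08
H	CAC	0.82
H	CAT	0.18
I	ATC	0.82
I	ATT	0.12
I	ATA	0.06
L	CTG	0.52
L	CTC	0.31
L	CTT	0.06
L	TTG	0.06
L	TTA	0.03
L	CTA	0.02
K	AAG	0.91
K	AAA	0.09
M	ATG	1.00
F	TTC	0.86
F	TTT	0.14
P	CCG	0.45
P	CCC	0.32
P	CCT	0.13
P	CCA	0.10
S	AGC	0.28
S	TCC	0.26
S	TCG	0.22
S	TCT	0.09
S	AGT	0.08
S	TCA	0.07
T	ACC	0.54
T	ACG	0.29
T	ACT	0.09
T	ACA	0.08
W	TGG	1.00
Y	TAC	0.83
Y	TAT	0.17
V	GTC	0.46
V	GTG	0.38
V	GTT	0.10
V	GTA	0.06
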