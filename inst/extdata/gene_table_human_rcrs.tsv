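# Human mitochondrial gene coordinates, rCRS frame (NC_012920), 1-based inclusive.
# Strand H = heavy (reference orientation), L = light (reverse complement).
# The control region spans the origin and is listed as two non-wrapping rows.
name	start	end	strand	kind
CR2	1	576	H	control
RNR1	648	1601	H	rRNA
RNR2	1671	3229	H	rRNA
TRNL1	3230	3304	H	tRNA
ND1	3307	4262	H	protein
ND2	4470	5511	H	protein
COI	5904	7445	H	protein
COII	7586	8269	H	protein
ATP8	8366	8572	H	protein
ATP6	8527	9207	H	protein
COIII	9207	9990	H	protein
ND3	10059	10404	H	protein
ND4L	10470	10766	H	protein
ND4	10760	12137	H	protein
ND5	12337	14148	H	protein
ND6	14149	14673	L	protein
CYTB	14747	15887	H	protein
CR1	16024	16569	H	control
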