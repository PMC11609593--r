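# cutoff=9.0
# Kyte-Doolittle hydropathy rescaled to [0, 1]: H = (KD + 4.5) / 9
ILE	1.0000
VAL	0.9667
LEU	0.9222
PHE	0.8111
CYS	0.7778
MET	0.7111
ALA	0.7000
GLY	0.4556
THR	0.4222
SER	0.4111
TRP	0.4000
TYR	0.3556
PRO	0.3222
HIS	0.1444
GLU	0.1111
GLN	0.1111
ASP	0.1111
ASN	0.1111
LYS	0.0667
ARG	0.0000
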