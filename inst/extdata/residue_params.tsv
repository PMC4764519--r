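code	hydrophobicity	charge	bead_radius
A	0.31	0	0.3
R	0	1	0.3
N	0.06	0	0.3
D	0.03	-1	0.3
C	0.68	0	0.3
Q	0.1	0	0.3
E	0.04	-1	0.3
G	0.11	0	0.3
H	0.33	0	0.3
I	0.92	0	0.3
L	0.92	0	0.3
K	0.07	1	0.3
M	0.75	0	0.3
F	1	0	0.3
P	0.37	0	0.3
S	0.12	0	0.3
T	0.21	0	0.3
W	0.95	0	0.3
Y	0.62	0	0.3
V	0.78	0	0.3
J	1	0	0.3
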