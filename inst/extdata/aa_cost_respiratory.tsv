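aa	atp
A	14.5
R	20.5
N	18.5
D	15.5
C	26.5
E	9.5
Q	10.5
G	14.5
H	29
I	38
L	37
K	36
M	36.5
F	61
P	14.5
S	14.5
T	21.5
W	75.5
Y	59
V	29
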