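amino_acid,count
F,50
H,26
I,34
K,92
L,116
M,14
T,112
V,128
W,25
A,68
Y,62
S,160
C,32
G,84
D,58
N,51
E,62
P,96
Q,63
R,35
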