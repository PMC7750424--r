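amino_acid,molecules_1e20
F,2.41
H,1.63
I,4.82
K,6.01
L,4.82
M,1.21
T,4.80
V,4.83
W,0.47
A,0
Y,3.45
S,2.41
C,3.11
G,2.41
D,0
N,0
E,0
P,0
Q,24.07
R,2.91
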