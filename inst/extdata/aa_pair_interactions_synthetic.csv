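residue,A,C,D,E,F,G,H,I,K,L,M,N,P,Q,R,S,T,V,W,Y
A,1,1,0,0,1,0,0,1,0,1,1,0,0,0,0,0,0,1,1,0
C,1,1.5,0.5,0.5,1,0,0.5,1,0.5,1,1.5,0.5,0,0.5,0.5,0.5,0.5,1,1.5,0.5
D,0,0.5,-2,-2,0,0,2.5,0,2.5,0,0,0.5,0,0.5,2.5,0.5,0.5,0,0.5,0.5
E,0,0.5,-2,-2,0,0,2.5,0,2.5,0,0,0.5,0,0.5,2.5,0.5,0.5,0,0.5,0.5
F,1,1,0,0,1.5,0,0.5,1,0,1,1,0,0,0,0,0,0,1,1.5,0.5
G,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
H,0,0.5,2.5,2.5,0.5,0,-1,0,-1.5,0,0.5,0.5,0,0.5,-1.5,0.5,0.5,0,1,1
I,1,1,0,0,1,0,0,1,0,1,1,0,0,0,0,0,0,1,1,0
K,0,0.5,2.5,2.5,0,0,-1.5,0,-2,0,0.5,0.5,0,0.5,-2,0.5,0.5,0,0,0.5
L,1,1,0,0,1,0,0,1,0,1,1,0,0,0,0,0,0,1,1,0
M,1,1.5,0,0,1,0,0.5,1,0.5,1,1,0.5,0,0.5,0.5,0.5,0.5,1,1.5,0.5
N,0,0.5,0.5,0.5,0,0,0.5,0,0.5,0,0.5,0.5,0,0.5,0.5,0.5,0.5,0,0.5,0.5
P,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Q,0,0.5,0.5,0.5,0,0,0.5,0,0.5,0,0.5,0.5,0,0.5,0.5,0.5,0.5,0,0.5,0.5
R,0,0.5,2.5,2.5,0,0,-1.5,0,-2,0,0.5,0.5,0,0.5,-2,0.5,0.5,0,0,0.5
S,0,0.5,0.5,0.5,0,0,0.5,0,0.5,0,0.5,0.5,0,0.5,0.5,0.5,0.5,0,0.5,0.5
T,0,0.5,0.5,0.5,0,0,0.5,0,0.5,0,0.5,0.5,0,0.5,0.5,0.5,0.5,0,0.5,0.5
V,1,1,0,0,1,0,0,1,0,1,1,0,0,0,0,0,0,1,1,0
W,1,1.5,0.5,0.5,1.5,0,1,1,0,1,1.5,0.5,0,0.5,0,0.5,0.5,1,1.5,1
Y,0,0.5,0.5,0.5,0.5,0,1,0,0.5,0,0.5,0.5,0,0.5,0.5,0.5,0.5,0,1,1
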