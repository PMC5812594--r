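,A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,V,Y
A,0.08,0.05,0,0,0,0.04,0.05,0,0,0,0,0.05,0,0,-2,0,0,0,0,0
R,0.05,0,0.1,0.3,0,0.2,0.6,0,0,0,0,0,0,0,-2,0,0,0,0,0
N,0,0.1,0.04,0,0,0,0.1,0,0,0,0,0.1,0,0,-2,0,0,0,0,0
D,0,0.5,0,0,0,0,0,0,0,0,0,0.35,0,0,-2,0,0,0,0,0
C,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
Q,0.04,0.2,0,0,0,0.08,0.2,0,0,0,0,0.2,0,0,-2,0,0,0,0,0
E,0.05,1,0.1,0,0,0.2,0,0,0,0,0,0.7,0,0,-2,0,0,0,0,0
G,0,0,0,0,0,0,0,-0.5,0,0,0,0,0,0,-2,0,0,0,0,0
H,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
I,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
L,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
K,0.05,0,0.1,0.25,0,0.2,0.5,0,0,0,0,0,0,0,-2,0,0,0,0,0
M,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
F,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
P,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2,-2
S,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
T,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
W,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
V,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
Y,0,0,0,0,0,0,0,0,0,0,0,0,0,0,-2,0,0,0,0,0
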