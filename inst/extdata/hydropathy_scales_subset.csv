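one_letter,KYTJ820101,HOPP,EISEN,JANIN,FAUCH,WIMLEY
A,1.8,-0.5,0.62,0.3,0.31,-0.17
R,-4.5,3.0,-2.53,-1.4,-1.01,-0.81
N,-3.5,0.2,-0.78,-0.5,-0.60,-0.42
D,-3.5,3.0,-0.90,-0.6,-0.77,-1.23
C,2.5,-1.0,0.29,0.9,1.54,0.24
Q,-3.5,0.2,-0.85,-0.7,-0.22,-0.58
E,-3.5,3.0,-0.74,-0.7,-0.64,-2.02
G,-0.4,0.0,0.48,0.3,0.00,-0.01
H,-3.2,-0.5,-0.40,-0.1,0.13,-0.17
I,4.5,-1.8,1.38,0.7,1.80,0.31
L,3.8,-1.8,1.06,0.5,1.70,0.56
K,-3.9,3.0,-1.50,-1.8,-0.99,-0.99
M,1.9,-1.3,0.64,0.4,1.23,0.23
F,2.8,-2.5,1.19,0.5,1.79,1.13
P,-1.6,0.0,0.12,-0.3,0.72,-0.45
S,-0.8,0.3,-0.18,-0.1,-0.04,-0.13
T,-0.7,-0.4,-0.05,-0.2,0.26,-0.14
W,-0.9,-3.4,0.81,0.3,2.25,1.85
Y,-1.3,-2.3,0.26,-0.4,0.96,0.94
V,4.2,-1.5,1.08,0.6,1.22,-0.07
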