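one_letter,lambda,sigma_nm,charge,mass_Da,pKa
A,0.274329796904035,0.504,0,71.0788,NA
R,0.730762476751717,0.656,1,156.1875,NA
N,0.425585900978771,0.568,0,114.1038,NA
D,0.0416040480605567,0.558,-1,115.0886,NA
C,0.561543509914178,0.548,0,103.1388,NA
Q,0.393431855105604,0.602,0,128.1307,NA
E,0.0006935460962935,0.592,-1,129.1155,NA
G,0.70588437336664,0.45,0,57.0519,NA
H,0.466366729055799,0.608,0,137.1411,6
I,0.542362361067189,0.618,0,113.1594,NA
L,0.644000500778223,0.618,0,113.1594,NA
K,0.179021173899058,0.636,1,128.1741,NA
M,0.53084811343375,0.618,0,131.1926,NA
F,0.867235898206298,0.636,0,147.1766,NA
P,0.359312657636464,0.556,0,97.1167,NA
S,0.462541681161154,0.518,0,87.0782,NA
T,0.371316297627396,0.562,0,101.1051,NA
W,0.989376474037164,0.678,0,186.2132,NA
Y,0.977461144934346,0.646,0,163.176,NA
V,0.208376960817448,0.586,0,99.1326,NA
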