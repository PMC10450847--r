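one_letter,lambda,sigma_nm,charge,mass_Da,pKa
A,0.0011162643859539,0.504,0,71.0788,NA
R,0.724991594771521,0.656,1,156.1875,NA
N,0.438327299702728,0.568,0,114.1038,NA
D,0.0291821237763497,0.558,-1,115.0886,NA
C,0.610137955399283,0.548,0,103.1388,NA
Q,0.326818805052521,0.602,0,128.1307,NA
E,0.0061002816086497,0.592,-1,129.1155,NA
G,0.701271367797246,0.45,0,57.0519,NA
H,0.465194808234698,0.608,0,137.1411,6
I,0.607526833084526,0.618,0,113.1594,NA
L,0.55630203057332,0.618,0,113.1594,NA
K,0.0586171731586979,0.636,1,128.1741,NA
M,0.745899342082671,0.618,0,131.1926,NA
F,0.921695983217594,0.636,0,147.1766,NA
P,0.372964185359935,0.556,0,97.1167,NA
S,0.464857013006561,0.518,0,87.0782,NA
T,0.537977761330702,0.562,0,101.1051,NA
W,0.984423547839393,0.678,0,186.2132,NA
Y,0.995010822959432,0.646,0,163.176,NA
V,0.418500685255987,0.586,0,99.1326,NA
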