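label,x,y,z
Fp1,-0.2939,0.9045,0.309
Fp2,0.2939,0.9045,0.309
F7,-0.7694,0.559,0.309
F3,-0.4677,0.5775,0.6691
Fz,0,0.5878,0.809
F4,0.4677,0.5775,0.6691
F8,0.7694,0.559,0.309
FC5,-0.8085,0.3104,0.5
FC1,-0.2876,0.2876,0.9135
FC2,0.2876,0.2876,0.9135
FC6,0.8085,0.3104,0.5
T7,-0.9511,0,0.309
C3,-0.5878,0,0.809
Cz,0,0,1
C2,0.309,0,0.9511
C4,0.5878,0,0.809
T8,0.9511,0,0.309
CP5,-0.8085,-0.3104,0.5
CP1,-0.2876,-0.2876,0.9135
CP2,0.2876,-0.2876,0.9135
CP6,0.8085,-0.3104,0.5
TP8,0.9045,-0.2939,0.309
P7,-0.7694,-0.559,0.309
P3,-0.4677,-0.5775,0.6691
Pz,0,-0.5878,0.809
P4,0.4677,-0.5775,0.6691
P8,0.7694,-0.559,0.309
P10,0.809,-0.5878,0
PO4,0.3277,-0.772,0.5446
PO8,0.559,-0.7694,0.309
Oz,0,-0.9511,0.309
O2,0.2939,-0.9045,0.309
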