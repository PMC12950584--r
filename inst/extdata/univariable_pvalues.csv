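variable,p_label,p
SBP-MI,<0.001,0.0005
INR,0.007,0.007
HBCDI,0.008,0.008
NE,0.018,0.018
ALB,0.021,0.021
CHE,0.022,0.022
Na,0.029,0.029
Previous history of SBP,0.057,0.057
Cr,0.070,0.070
Age,0.083,0.083
TBil,0.158,0.158
Gender,0.231,0.231
RBC,0.251,0.251
WBC,0.666,0.666
PLT,0.688,0.688
Diabetes,0.739,0.739
ALT,0.788,0.788
AST,0.808,0.808
log10HBV DNA,0.873,0.873
GLU,0.997,0.997
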