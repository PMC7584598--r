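residue,max_sasa_A2
ALA,129
ARG,274
ASN,195
ASP,193
CYS,167
GLN,225
GLU,223
GLY,104
HIS,224
ILE,197
LEU,201
LYS,236
MET,224
PHE,240
PRO,159
SER,155
THR,172
TRP,285
TYR,263
VAL,174
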