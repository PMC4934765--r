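residue,ref1,ref2,ref3
ALA,CB,CA,N
ARG,CZ,NH1,NH2
ASN,CG,OD1,ND2
ASP,CG,OD1,OD2
CYS,SG,CB,CA
GLN,CD,OE1,NE2
GLU,CD,OE1,OE2
GLY,CA,N,C
HIS,CG,ND1,NE2
ILE,CG1,CG2,CD1
LEU,CG,CD1,CD2
LYS,NZ,CE,CD
MET,SD,CG,CE
PHE,CG,CE1,CE2
PRO,CG,CB,CD
SER,OG,CB,CA
THR,OG1,CG2,CB
TRP,CG,NE1,CZ3
TYR,OH,CE1,CE2
VAL,CB,CG1,CG2
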