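species,atom1,atom2
frag_ALA,CA,CB
frag_ALA,CA,HA
frag_ALA,CB,HB1
frag_ALA,CB,HB2
frag_ALA,CB,HB3
frag_ALA,CA,HA2
frag_ALA,CA,HA3
frag_ARG,CA,CB
frag_ARG,CA,HA
frag_ARG,CB,CG
frag_ARG,CB,HB2
frag_ARG,CB,HB3
frag_ARG,CG,CD
frag_ARG,CG,HG2
frag_ARG,CG,HG3
frag_ARG,CD,NE
frag_ARG,CD,HD2
frag_ARG,CD,HD3
frag_ARG,NE,CZ
frag_ARG,NE,HE
frag_ARG,CZ,NH1
frag_ARG,CZ,NH2
frag_ARG,NH1,HH11
frag_ARG,NH1,HH12
frag_ARG,NH2,HH21
frag_ARG,NH2,HH22
frag_ARG,CA,HA2
frag_ARG,CA,HA3
frag_ASN,CA,CB
frag_ASN,CA,HA
frag_ASN,CB,CG
frag_ASN,CB,HB2
frag_ASN,CB,HB3
frag_ASN,CG,OD1
frag_ASN,CG,ND2
frag_ASN,ND2,HD21
frag_ASN,ND2,HD22
frag_ASN,CA,HA2
frag_ASN,CA,HA3
frag_ASP,CA,CB
frag_ASP,CA,HA
frag_ASP,CB,CG
frag_ASP,CB,HB2
frag_ASP,CB,HB3
frag_ASP,CG,OD1
frag_ASP,CG,OD2
frag_ASP,CA,HA2
frag_ASP,CA,HA3
frag_CYS,CA,CB
frag_CYS,CA,HA
frag_CYS,CB,SG
frag_CYS,CB,HB2
frag_CYS,CB,HB3
frag_CYS,SG,HG
frag_CYS,CA,HA2
frag_CYS,CA,HA3
frag_GLN,CA,CB
frag_GLN,CA,HA
frag_GLN,CB,CG
frag_GLN,CB,HB2
frag_GLN,CB,HB3
frag_GLN,CG,CD
frag_GLN,CG,HG2
frag_GLN,CG,HG3
frag_GLN,CD,OE1
frag_GLN,CD,NE2
frag_GLN,NE2,HE21
frag_GLN,NE2,HE22
frag_GLN,CA,HA2
frag_GLN,CA,HA3
frag_GLU,CA,CB
frag_GLU,CA,HA
frag_GLU,CB,CG
frag_GLU,CB,HB2
frag_GLU,CB,HB3
frag_GLU,CG,CD
frag_GLU,CG,HG2
frag_GLU,CG,HG3
frag_GLU,CD,OE1
frag_GLU,CD,OE2
frag_GLU,CA,HA2
frag_GLU,CA,HA3
frag_GLY,CA,HA2
frag_GLY,CA,HA3
frag_GLY,CA,HA1
frag_GLY,CA,HA4
frag_HIS,CA,CB
frag_HIS,CA,HA
frag_HIS,CB,CG
frag_HIS,CB,HB2
frag_HIS,CB,HB3
frag_HIS,CG,ND1
frag_HIS,CG,CD2
frag_HIS,ND1,CE1
frag_HIS,CD2,NE2
frag_HIS,CD2,HD2
frag_HIS,CE1,NE2
frag_HIS,CE1,HE1
frag_HIS,NE2,HE2
frag_HIS,CA,HA2
frag_HIS,CA,HA3
frag_ILE,CA,CB
frag_ILE,CA,HA
frag_ILE,CB,CG1
frag_ILE,CB,CG2
frag_ILE,CB,HB
frag_ILE,CG1,CD1
frag_ILE,CG1,HG12
frag_ILE,CG1,HG13
frag_ILE,CG2,HG21
frag_ILE,CG2,HG22
frag_ILE,CG2,HG23
frag_ILE,CD1,HD11
frag_ILE,CD1,HD12
frag_ILE,CD1,HD13
frag_ILE,CA,HA2
frag_ILE,CA,HA3
frag_LEU,CA,CB
frag_LEU,CA,HA
frag_LEU,CB,CG
frag_LEU,CB,HB2
frag_LEU,CB,HB3
frag_LEU,CG,CD1
frag_LEU,CG,CD2
frag_LEU,CG,HG
frag_LEU,CD1,HD11
frag_LEU,CD1,HD12
frag_LEU,CD1,HD13
frag_LEU,CD2,HD21
frag_LEU,CD2,HD22
frag_LEU,CD2,HD23
frag_LEU,CA,HA2
frag_LEU,CA,HA3
frag_LYS,CA,CB
frag_LYS,CA,HA
frag_LYS,CB,CG
frag_LYS,CB,HB2
frag_LYS,CB,HB3
frag_LYS,CG,CD
frag_LYS,CG,HG2
frag_LYS,CG,HG3
frag_LYS,CD,CE
frag_LYS,CD,HD2
frag_LYS,CD,HD3
frag_LYS,CE,NZ
frag_LYS,CE,HE2
frag_LYS,CE,HE3
frag_LYS,NZ,HZ1
frag_LYS,NZ,HZ2
frag_LYS,NZ,HZ3
frag_LYS,CA,HA2
frag_LYS,CA,HA3
frag_MET,CA,CB
frag_MET,CA,HA
frag_MET,CB,CG
frag_MET,CB,HB2
frag_MET,CB,HB3
frag_MET,CG,SD
frag_MET,CG,HG2
frag_MET,CG,HG3
frag_MET,SD,CE
frag_MET,CE,HE1
frag_MET,CE,HE2
frag_MET,CE,HE3
frag_MET,CA,HA2
frag_MET,CA,HA3
frag_PHE,CA,CB
frag_PHE,CA,HA
frag_PHE,CB,CG
frag_PHE,CB,HB2
frag_PHE,CB,HB3
frag_PHE,CG,CD1
frag_PHE,CG,CD2
frag_PHE,CD1,CE1
frag_PHE,CD1,HD1
frag_PHE,CD2,CE2
frag_PHE,CD2,HD2
frag_PHE,CE1,CZ
frag_PHE,CE1,HE1
frag_PHE,CE2,CZ
frag_PHE,CE2,HE2
frag_PHE,CZ,HZ
frag_PHE,CA,HA2
frag_PHE,CA,HA3
frag_PRO,N,CA
frag_PRO,N,CD
frag_PRO,CA,CB
frag_PRO,CA,HA
frag_PRO,CB,CG
frag_PRO,CB,HB2
frag_PRO,CB,HB3
frag_PRO,CG,CD
frag_PRO,CG,HG2
frag_PRO,CG,HG3
frag_PRO,CD,HD2
frag_PRO,CD,HD3
frag_PRO,N,H1
frag_SER,CA,CB
frag_SER,CA,HA
frag_SER,CB,OG
frag_SER,CB,HB2
frag_SER,CB,HB3
frag_SER,OG,HG
frag_SER,CA,HA2
frag_SER,CA,HA3
frag_THR,CA,CB
frag_THR,CA,HA
frag_THR,CB,OG1
frag_THR,CB,CG2
frag_THR,CB,HB
frag_THR,OG1,HG1
frag_THR,CG2,HG21
frag_THR,CG2,HG22
frag_THR,CG2,HG23
frag_THR,CA,HA2
frag_THR,CA,HA3
frag_TRP,CA,CB
frag_TRP,CA,HA
frag_TRP,CB,CG
frag_TRP,CB,HB2
frag_TRP,CB,HB3
frag_TRP,CG,CD1
frag_TRP,CG,CD2
frag_TRP,CD1,NE1
frag_TRP,CD1,HD1
frag_TRP,CD2,CE2
frag_TRP,CD2,CE3
frag_TRP,NE1,CE2
frag_TRP,NE1,HE1
frag_TRP,CE2,CZ2
frag_TRP,CE3,CZ3
frag_TRP,CE3,HE3
frag_TRP,CZ2,CH2
frag_TRP,CZ2,HZ2
frag_TRP,CZ3,CH2
frag_TRP,CZ3,HZ3
frag_TRP,CH2,HH2
frag_TRP,CA,HA2
frag_TRP,CA,HA3
frag_TYR,CA,CB
frag_TYR,CA,HA
frag_TYR,CB,CG
frag_TYR,CB,HB2
frag_TYR,CB,HB3
frag_TYR,CG,CD1
frag_TYR,CG,CD2
frag_TYR,CD1,CE1
frag_TYR,CD1,HD1
frag_TYR,CD2,CE2
frag_TYR,CD2,HD2
frag_TYR,CE1,CZ
frag_TYR,CE1,HE1
frag_TYR,CE2,CZ
frag_TYR,CE2,HE2
frag_TYR,CZ,OH
frag_TYR,OH,HH
frag_TYR,CA,HA2
frag_TYR,CA,HA3
frag_VAL,CA,CB
frag_VAL,CA,HA
frag_VAL,CB,CG1
frag_VAL,CB,CG2
frag_VAL,CB,HB
frag_VAL,CG1,HG11
frag_VAL,CG1,HG12
frag_VAL,CG1,HG13
frag_VAL,CG2,HG21
frag_VAL,CG2,HG22
frag_VAL,CG2,HG23
frag_VAL,CA,HA2
frag_VAL,CA,HA3
nuc_DA,P,OP1
nuc_DA,P,OP2
nuc_DA,P,O5'
nuc_DA,O5',C5'
nuc_DA,C5',C4'
nuc_DA,C5',H5'
nuc_DA,C5',H5''
nuc_DA,C4',O4'
nuc_DA,C4',C3'
nuc_DA,C4',H4'
nuc_DA,O4',C1'
nuc_DA,C3',O3'
nuc_DA,C3',C2'
nuc_DA,C3',H3'
nuc_DA,O3',HO3'
nuc_DA,C2',C1'
nuc_DA,C2',H2'
nuc_DA,C2',H2''
nuc_DA,C1',N9
nuc_DA,C1',H1'
nuc_DA,N9,C8
nuc_DA,N9,C4
nuc_DA,C8,N7
nuc_DA,C8,H8
nuc_DA,N7,C5
nuc_DA,C5,C6
nuc_DA,C5,C4
nuc_DA,C6,N6
nuc_DA,C6,N1
nuc_DA,N6,H61
nuc_DA,N6,H62
nuc_DA,N1,C2
nuc_DA,C2,N3
nuc_DA,C2,H2
nuc_DA,N3,C4
nuc_DA,P,O3T
nuc_DA,O3T,HO3T
base_DA,N9,C8
base_DA,N9,C4
base_DA,C8,N7
base_DA,C8,H8
base_DA,N7,C5
base_DA,C5,C6
base_DA,C5,C4
base_DA,C6,N6
base_DA,C6,N1
base_DA,N6,H61
base_DA,N6,H62
base_DA,N1,C2
base_DA,C2,N3
base_DA,C2,H2
base_DA,N3,C4
base_DA,N9,H9
nuc_DC,P,OP1
nuc_DC,P,OP2
nuc_DC,P,O5'
nuc_DC,O5',C5'
nuc_DC,C5',C4'
nuc_DC,C5',H5'
nuc_DC,C5',H5''
nuc_DC,C4',O4'
nuc_DC,C4',C3'
nuc_DC,C4',H4'
nuc_DC,O4',C1'
nuc_DC,C3',O3'
nuc_DC,C3',C2'
nuc_DC,C3',H3'
nuc_DC,O3',HO3'
nuc_DC,C2',C1'
nuc_DC,C2',H2'
nuc_DC,C2',H2''
nuc_DC,C1',N1
nuc_DC,C1',H1'
nuc_DC,N1,C2
nuc_DC,N1,C6
nuc_DC,C2,O2
nuc_DC,C2,N3
nuc_DC,N3,C4
nuc_DC,C4,N4
nuc_DC,C4,C5
nuc_DC,N4,H41
nuc_DC,N4,H42
nuc_DC,C5,C6
nuc_DC,C5,H5
nuc_DC,C6,H6
nuc_DC,P,O3T
nuc_DC,O3T,HO3T
base_DC,N1,C2
base_DC,N1,C6
base_DC,C2,O2
base_DC,C2,N3
base_DC,N3,C4
base_DC,C4,N4
base_DC,C4,C5
base_DC,N4,H41
base_DC,N4,H42
base_DC,C5,C6
base_DC,C5,H5
base_DC,C6,H6
base_DC,N1,H1
nuc_DG,P,OP1
nuc_DG,P,OP2
nuc_DG,P,O5'
nuc_DG,O5',C5'
nuc_DG,C5',C4'
nuc_DG,C5',H5'
nuc_DG,C5',H5''
nuc_DG,C4',O4'
nuc_DG,C4',C3'
nuc_DG,C4',H4'
nuc_DG,O4',C1'
nuc_DG,C3',O3'
nuc_DG,C3',C2'
nuc_DG,C3',H3'
nuc_DG,O3',HO3'
nuc_DG,C2',C1'
nuc_DG,C2',H2'
nuc_DG,C2',H2''
nuc_DG,C1',N9
nuc_DG,C1',H1'
nuc_DG,N9,C8
nuc_DG,N9,C4
nuc_DG,C8,N7
nuc_DG,C8,H8
nuc_DG,N7,C5
nuc_DG,C5,C6
nuc_DG,C5,C4
nuc_DG,C6,O6
nuc_DG,C6,N1
nuc_DG,N1,C2
nuc_DG,N1,H1
nuc_DG,C2,N2
nuc_DG,C2,N3
nuc_DG,N2,H21
nuc_DG,N2,H22
nuc_DG,N3,C4
nuc_DG,P,O3T
nuc_DG,O3T,HO3T
base_DG,N9,C8
base_DG,N9,C4
base_DG,C8,N7
base_DG,C8,H8
base_DG,N7,C5
base_DG,C5,C6
base_DG,C5,C4
base_DG,C6,O6
base_DG,C6,N1
base_DG,N1,C2
base_DG,N1,H1
base_DG,C2,N2
base_DG,C2,N3
base_DG,N2,H21
base_DG,N2,H22
base_DG,N3,C4
base_DG,N9,H9
nuc_DT,P,OP1
nuc_DT,P,OP2
nuc_DT,P,O5'
nuc_DT,O5',C5'
nuc_DT,C5',C4'
nuc_DT,C5',H5'
nuc_DT,C5',H5''
nuc_DT,C4',O4'
nuc_DT,C4',C3'
nuc_DT,C4',H4'
nuc_DT,O4',C1'
nuc_DT,C3',O3'
nuc_DT,C3',C2'
nuc_DT,C3',H3'
nuc_DT,O3',HO3'
nuc_DT,C2',C1'
nuc_DT,C2',H2'
nuc_DT,C2',H2''
nuc_DT,C1',N1
nuc_DT,C1',H1'
nuc_DT,N1,C2
nuc_DT,N1,C6
nuc_DT,C2,O2
nuc_DT,C2,N3
nuc_DT,N3,C4
nuc_DT,N3,H3
nuc_DT,C4,O4
nuc_DT,C4,C5
nuc_DT,C5,C7
nuc_DT,C5,C6
nuc_DT,C7,H71
nuc_DT,C7,H72
nuc_DT,C7,H73
nuc_DT,C6,H6
nuc_DT,P,O3T
nuc_DT,O3T,HO3T
base_DT,N1,C2
base_DT,N1,C6
base_DT,C2,O2
base_DT,C2,N3
base_DT,N3,C4
base_DT,N3,H3
base_DT,C4,O4
base_DT,C4,C5
base_DT,C5,C7
base_DT,C5,C6
base_DT,C7,H71
base_DT,C7,H72
base_DT,C7,H73
base_DT,C6,H6
base_DT,N1,H1
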