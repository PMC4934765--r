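species,atom1,atom2,atom3,atom4,k_kj,n,gamma_deg
frag_ARG,HA,CA,CB,CG,1.5,3,0.0
frag_ARG,HG2,CG,CB,CA,1.5,3,0.0
frag_ARG,HG3,CG,CB,CA,1.5,3,0.0
frag_ARG,HD2,CD,CG,CB,1.5,3,0.0
frag_ARG,HD3,CD,CG,CB,1.5,3,0.0
frag_ARG,HE,NE,CD,CG,25.0,2,180.0
frag_ARG,HH11,NH1,CZ,NE,25.0,2,180.0
frag_ARG,HH12,NH1,CZ,NE,25.0,2,180.0
frag_ARG,HH21,NH2,CZ,NE,25.0,2,180.0
frag_ARG,HH22,NH2,CZ,NE,25.0,2,180.0
frag_ARG,HA2,CA,CB,CG,1.5,3,0.0
frag_ARG,HA3,CA,CB,CG,1.5,3,0.0
frag_ASN,HA,CA,CB,CG,1.5,3,0.0
frag_ASN,HD21,ND2,CG,OD1,25.0,2,180.0
frag_ASN,HD22,ND2,CG,OD1,25.0,2,180.0
frag_ASN,HA2,CA,CB,CG,1.5,3,0.0
frag_ASN,HA3,CA,CB,CG,1.5,3,0.0
frag_ASP,HA,CA,CB,CG,1.5,3,0.0
frag_ASP,HA2,CA,CB,CG,1.5,3,0.0
frag_ASP,HA3,CA,CB,CG,1.5,3,0.0
frag_CYS,HA,CA,CB,SG,1.5,3,0.0
frag_CYS,HG,SG,CB,CA,1.5,3,0.0
frag_CYS,HA2,CA,CB,SG,1.5,3,0.0
frag_CYS,HA3,CA,CB,SG,1.5,3,0.0
frag_GLN,HA,CA,CB,CG,1.5,3,0.0
frag_GLN,HG2,CG,CB,CA,1.5,3,0.0
frag_GLN,HG3,CG,CB,CA,1.5,3,0.0
frag_GLN,HE21,NE2,CD,OE1,25.0,2,180.0
frag_GLN,HE22,NE2,CD,OE1,25.0,2,180.0
frag_GLN,HA2,CA,CB,CG,1.5,3,0.0
frag_GLN,HA3,CA,CB,CG,1.5,3,0.0
frag_GLU,HA,CA,CB,CG,1.5,3,0.0
frag_GLU,HG2,CG,CB,CA,1.5,3,0.0
frag_GLU,HG3,CG,CB,CA,1.5,3,0.0
frag_GLU,HA2,CA,CB,CG,1.5,3,0.0
frag_GLU,HA3,CA,CB,CG,1.5,3,0.0
frag_HIS,HA,CA,CB,CG,1.5,3,0.0
frag_HIS,HD2,CD2,CG,CB,1.5,3,0.0
frag_HIS,HE1,CE1,ND1,CG,1.5,3,0.0
frag_HIS,HE2,NE2,CD2,CG,25.0,2,180.0
frag_HIS,HA2,CA,CB,CG,1.5,3,0.0
frag_HIS,HA3,CA,CB,CG,1.5,3,0.0
frag_ILE,HA,CA,CB,CG1,1.5,3,0.0
frag_ILE,HG12,CG1,CB,CA,1.5,3,0.0
frag_ILE,HG13,CG1,CB,CA,1.5,3,0.0
frag_ILE,HG21,CG2,CB,CA,1.5,3,0.0
frag_ILE,HG22,CG2,CB,CA,1.5,3,0.0
frag_ILE,HG23,CG2,CB,CA,1.5,3,0.0
frag_ILE,HD11,CD1,CG1,CB,1.5,3,0.0
frag_ILE,HD12,CD1,CG1,CB,1.5,3,0.0
frag_ILE,HD13,CD1,CG1,CB,1.5,3,0.0
frag_ILE,HA2,CA,CB,CG1,1.5,3,0.0
frag_ILE,HA3,CA,CB,CG1,1.5,3,0.0
frag_LEU,HA,CA,CB,CG,1.5,3,0.0
frag_LEU,HG,CG,CB,CA,1.5,3,0.0
frag_LEU,HD11,CD1,CG,CB,1.5,3,0.0
frag_LEU,HD12,CD1,CG,CB,1.5,3,0.0
frag_LEU,HD13,CD1,CG,CB,1.5,3,0.0
frag_LEU,HD21,CD2,CG,CB,1.5,3,0.0
frag_LEU,HD22,CD2,CG,CB,1.5,3,0.0
frag_LEU,HD23,CD2,CG,CB,1.5,3,0.0
frag_LEU,HA2,CA,CB,CG,1.5,3,0.0
frag_LEU,HA3,CA,CB,CG,1.5,3,0.0
frag_LYS,HA,CA,CB,CG,1.5,3,0.0
frag_LYS,HG2,CG,CB,CA,1.5,3,0.0
frag_LYS,HG3,CG,CB,CA,1.5,3,0.0
frag_LYS,HD2,CD,CG,CB,1.5,3,0.0
frag_LYS,HD3,CD,CG,CB,1.5,3,0.0
frag_LYS,HE2,CE,CD,CG,1.5,3,0.0
frag_LYS,HE3,CE,CD,CG,1.5,3,0.0
frag_LYS,HZ1,NZ,CE,CD,1.5,3,0.0
frag_LYS,HZ2,NZ,CE,CD,1.5,3,0.0
frag_LYS,HZ3,NZ,CE,CD,1.5,3,0.0
frag_LYS,HA2,CA,CB,CG,1.5,3,0.0
frag_LYS,HA3,CA,CB,CG,1.5,3,0.0
frag_MET,HA,CA,CB,CG,1.5,3,0.0
frag_MET,HG2,CG,CB,CA,1.5,3,0.0
frag_MET,HG3,CG,CB,CA,1.5,3,0.0
frag_MET,HE1,CE,SD,CG,1.5,3,0.0
frag_MET,HE2,CE,SD,CG,1.5,3,0.0
frag_MET,HE3,CE,SD,CG,1.5,3,0.0
frag_MET,HA2,CA,CB,CG,1.5,3,0.0
frag_MET,HA3,CA,CB,CG,1.5,3,0.0
frag_PHE,HA,CA,CB,CG,1.5,3,0.0
frag_PHE,HD1,CD1,CG,CB,1.5,3,0.0
frag_PHE,HD2,CD2,CG,CB,1.5,3,0.0
frag_PHE,HE1,CE1,CD1,CG,1.5,3,0.0
frag_PHE,HE2,CE2,CD2,CG,1.5,3,0.0
frag_PHE,HZ,CZ,CE1,CD1,1.5,3,0.0
frag_PHE,HA2,CA,CB,CG,1.5,3,0.0
frag_PHE,HA3,CA,CB,CG,1.5,3,0.0
frag_PRO,HA,CA,N,CD,1.5,3,0.0
frag_PRO,HB2,CB,CA,N,1.5,3,0.0
frag_PRO,HB3,CB,CA,N,1.5,3,0.0
frag_PRO,HG2,CG,CB,CA,1.5,3,0.0
frag_PRO,HG3,CG,CB,CA,1.5,3,0.0
frag_PRO,HD2,CD,N,CA,1.5,3,0.0
frag_PRO,HD3,CD,N,CA,1.5,3,0.0
frag_PRO,H1,N,CA,CB,1.5,3,0.0
frag_SER,HA,CA,CB,OG,1.5,3,0.0
frag_SER,HG,OG,CB,CA,1.5,3,0.0
frag_SER,HA2,CA,CB,OG,1.5,3,0.0
frag_SER,HA3,CA,CB,OG,1.5,3,0.0
frag_THR,HA,CA,CB,OG1,1.5,3,0.0
frag_THR,HG1,OG1,CB,CA,1.5,3,0.0
frag_THR,HG21,CG2,CB,CA,1.5,3,0.0
frag_THR,HG22,CG2,CB,CA,1.5,3,0.0
frag_THR,HG23,CG2,CB,CA,1.5,3,0.0
frag_THR,HA2,CA,CB,OG1,1.5,3,0.0
frag_THR,HA3,CA,CB,OG1,1.5,3,0.0
frag_TRP,HA,CA,CB,CG,1.5,3,0.0
frag_TRP,HD1,CD1,CG,CB,1.5,3,0.0
frag_TRP,HE1,NE1,CD1,CG,25.0,2,180.0
frag_TRP,HE3,CE3,CD2,CG,1.5,3,0.0
frag_TRP,HZ2,CZ2,CE2,CD2,1.5,3,0.0
frag_TRP,HZ3,CZ3,CE3,CD2,1.5,3,0.0
frag_TRP,HH2,CH2,CZ2,CE2,1.5,3,0.0
frag_TRP,HA2,CA,CB,CG,1.5,3,0.0
frag_TRP,HA3,CA,CB,CG,1.5,3,0.0
frag_TYR,HA,CA,CB,CG,1.5,3,0.0
frag_TYR,HD1,CD1,CG,CB,1.5,3,0.0
frag_TYR,HD2,CD2,CG,CB,1.5,3,0.0
frag_TYR,HE1,CE1,CD1,CG,1.5,3,0.0
frag_TYR,HE2,CE2,CD2,CG,1.5,3,0.0
frag_TYR,HH,OH,CZ,CE1,1.5,3,0.0
frag_TYR,HA2,CA,CB,CG,1.5,3,0.0
frag_TYR,HA3,CA,CB,CG,1.5,3,0.0
frag_VAL,HA,CA,CB,CG1,1.5,3,0.0
frag_VAL,HG11,CG1,CB,CA,1.5,3,0.0
frag_VAL,HG12,CG1,CB,CA,1.5,3,0.0
frag_VAL,HG13,CG1,CB,CA,1.5,3,0.0
frag_VAL,HG21,CG2,CB,CA,1.5,3,0.0
frag_VAL,HG22,CG2,CB,CA,1.5,3,0.0
frag_VAL,HG23,CG2,CB,CA,1.5,3,0.0
frag_VAL,HA2,CA,CB,CG1,1.5,3,0.0
frag_VAL,HA3,CA,CB,CG1,1.5,3,0.0
nuc_DA,H5',C5',O5',P,1.5,3,0.0
nuc_DA,H5'',C5',O5',P,1.5,3,0.0
nuc_DA,H4',C4',C5',O5',1.5,3,0.0
nuc_DA,H3',C3',C4',C5',1.5,3,0.0
nuc_DA,HO3',O3',C3',C4',1.5,3,0.0
nuc_DA,H2',C2',C3',C4',1.5,3,0.0
nuc_DA,H2'',C2',C3',C4',1.5,3,0.0
nuc_DA,H1',C1',O4',C4',1.5,3,0.0
nuc_DA,H8,C8,N9,C1',1.5,3,0.0
nuc_DA,H61,N6,C6,N1,25.0,2,180.0
nuc_DA,H62,N6,C6,N1,25.0,2,180.0
nuc_DA,H2,C2,N1,C6,1.5,3,0.0
nuc_DA,HO3T,O3T,P,OP1,1.5,3,0.0
base_DA,H8,C8,N9,C4,1.5,3,0.0
base_DA,H61,N6,C6,N1,25.0,2,180.0
base_DA,H62,N6,C6,N1,25.0,2,180.0
base_DA,H2,C2,N1,C6,1.5,3,0.0
base_DA,H9,N9,C8,N7,25.0,2,180.0
nuc_DC,H5',C5',O5',P,1.5,3,0.0
nuc_DC,H5'',C5',O5',P,1.5,3,0.0
nuc_DC,H4',C4',C5',O5',1.5,3,0.0
nuc_DC,H3',C3',C4',C5',1.5,3,0.0
nuc_DC,HO3',O3',C3',C4',1.5,3,0.0
nuc_DC,H2',C2',C3',C4',1.5,3,0.0
nuc_DC,H2'',C2',C3',C4',1.5,3,0.0
nuc_DC,H1',C1',O4',C4',1.5,3,0.0
nuc_DC,H41,N4,C4,N3,25.0,2,180.0
nuc_DC,H42,N4,C4,N3,25.0,2,180.0
nuc_DC,H5,C5,C4,N3,1.5,3,0.0
nuc_DC,H6,C6,N1,C1',1.5,3,0.0
nuc_DC,HO3T,O3T,P,OP1,1.5,3,0.0
base_DC,H41,N4,C4,N3,25.0,2,180.0
base_DC,H42,N4,C4,N3,25.0,2,180.0
base_DC,H5,C5,C4,N3,1.5,3,0.0
base_DC,H6,C6,N1,C2,1.5,3,0.0
base_DC,H1,N1,C2,O2,25.0,2,180.0
nuc_DG,H5',C5',O5',P,1.5,3,0.0
nuc_DG,H5'',C5',O5',P,1.5,3,0.0
nuc_DG,H4',C4',C5',O5',1.5,3,0.0
nuc_DG,H3',C3',C4',C5',1.5,3,0.0
nuc_DG,HO3',O3',C3',C4',1.5,3,0.0
nuc_DG,H2',C2',C3',C4',1.5,3,0.0
nuc_DG,H2'',C2',C3',C4',1.5,3,0.0
nuc_DG,H1',C1',O4',C4',1.5,3,0.0
nuc_DG,H8,C8,N9,C1',1.5,3,0.0
nuc_DG,H1,N1,C6,O6,25.0,2,180.0
nuc_DG,H21,N2,C2,N1,25.0,2,180.0
nuc_DG,H22,N2,C2,N1,25.0,2,180.0
nuc_DG,HO3T,O3T,P,OP1,1.5,3,0.0
base_DG,H8,C8,N9,C4,1.5,3,0.0
base_DG,H1,N1,C6,O6,25.0,2,180.0
base_DG,H21,N2,C2,N1,25.0,2,180.0
base_DG,H22,N2,C2,N1,25.0,2,180.0
base_DG,H9,N9,C8,N7,25.0,2,180.0
nuc_DT,H5',C5',O5',P,1.5,3,0.0
nuc_DT,H5'',C5',O5',P,1.5,3,0.0
nuc_DT,H4',C4',C5',O5',1.5,3,0.0
nuc_DT,H3',C3',C4',C5',1.5,3,0.0
nuc_DT,HO3',O3',C3',C4',1.5,3,0.0
nuc_DT,H2',C2',C3',C4',1.5,3,0.0
nuc_DT,H2'',C2',C3',C4',1.5,3,0.0
nuc_DT,H1',C1',O4',C4',1.5,3,0.0
nuc_DT,H3,N3,C2,O2,25.0,2,180.0
nuc_DT,H71,C7,C5,C4,1.5,3,0.0
nuc_DT,H72,C7,C5,C4,1.5,3,0.0
nuc_DT,H73,C7,C5,C4,1.5,3,0.0
nuc_DT,H6,C6,N1,C1',1.5,3,0.0
nuc_DT,HO3T,O3T,P,OP1,1.5,3,0.0
base_DT,H3,N3,C2,O2,25.0,2,180.0
base_DT,H71,C7,C5,C4,1.5,3,0.0
base_DT,H72,C7,C5,C4,1.5,3,0.0
base_DT,H73,C7,C5,C4,1.5,3,0.0
base_DT,H6,C6,N1,C2,1.5,3,0.0
base_DT,H1,N1,C2,O2,25.0,2,180.0
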