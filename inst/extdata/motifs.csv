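motif,residue,base_species,atom,element,x,y,z
asn_ade_hoogsteen,ASN,base_DA,N,N,5.269,4.769,6.255
asn_ade_hoogsteen,ASN,base_DA,CA,C,6.24,4.293,5.26
asn_ade_hoogsteen,ASN,base_DA,C,C,7.431,5.216,5.24
asn_ade_hoogsteen,ASN,base_DA,O,O,7.336,6.335,5.684
asn_ade_hoogsteen,ASN,base_DA,CB,C,5.585,4.276,3.876
asn_ade_hoogsteen,ASN,base_DA,CG,C,4.469,3.264,3.861
asn_ade_hoogsteen,ASN,base_DA,OD1,O,4.223,2.619,4.859
asn_ade_hoogsteen,ASN,base_DA,ND2,N,3.747,3.074,2.74
gln_ade_hoogsteen,GLN,base_DA,N,N,8.47,4.712,4.401
gln_ade_hoogsteen,GLN,base_DA,CA,C,7.397,5.289,5.223
gln_ade_hoogsteen,GLN,base_DA,C,C,7.895,5.488,6.63
gln_ade_hoogsteen,GLN,base_DA,O,O,8.739,4.753,7.082
gln_ade_hoogsteen,GLN,base_DA,CB,C,6.199,4.339,5.234
gln_ade_hoogsteen,GLN,base_DA,CG,C,5.695,4.135,3.805
gln_ade_hoogsteen,GLN,base_DA,CD,C,4.514,3.199,3.816
gln_ade_hoogsteen,GLN,base_DA,OE1,O,4.116,2.74,4.865
gln_ade_hoogsteen,GLN,base_DA,NE2,N,3.9,2.872,2.663
arg_gua_hoogsteen,ARG,base_DG,N,N,-10.255,6.133,-4.408
arg_gua_hoogsteen,ARG,base_DG,CA,C,-10.388,4.982,-3.516
arg_gua_hoogsteen,ARG,base_DG,C,C,-10.894,5.481,-2.174
arg_gua_hoogsteen,ARG,base_DG,O,O,-11.077,6.653,-1.876
arg_gua_hoogsteen,ARG,base_DG,CB,C,-9.065,4.213,-3.383
arg_gua_hoogsteen,ARG,base_DG,CG,C,-7.925,5.014,-2.735
arg_gua_hoogsteen,ARG,base_DG,CD,C,-6.65,4.188,-2.575
arg_gua_hoogsteen,ARG,base_DG,NE,N,-6.168,3.727,-3.854
arg_gua_hoogsteen,ARG,base_DG,CZ,C,-5.009,2.944,-3.999
arg_gua_hoogsteen,ARG,base_DG,NH1,N,-4.582,2.521,-5.253
arg_gua_hoogsteen,ARG,base_DG,NH2,N,-4.274,2.581,-2.875
ser_ade_hoogsteen,SER,base_DA,N,N,5.011,5.003,4.176
ser_ade_hoogsteen,SER,base_DA,CA,C,5.577,3.785,3.578
ser_ade_hoogsteen,SER,base_DA,C,C,6.592,4.165,2.532
ser_ade_hoogsteen,SER,base_DA,O,O,6.469,5.198,1.918
ser_ade_hoogsteen,SER,base_DA,CB,C,4.458,2.97,2.932
ser_ade_hoogsteen,SER,base_DA,OG,O,3.495,2.61,3.922
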