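base,atom,element,x,y,z
DA,N9,N,-1.291,4.498,0.0
DA,C8,C,0.003,4.924,0.0
DA,N7,N,0.807,3.901,0.0
DA,C5,C,0.082,2.757,0.0
DA,C6,C,0.397,1.387,0.0
DA,N6,N,1.714,0.963,0.0
DA,N1,N,-0.601,0.509,0.0
DA,C2,C,-1.859,0.904,0.0
DA,N3,N,-2.201,2.175,0.0
DA,C4,C,-1.273,3.126,0.0
DA,C1',C,-2.479,5.346,0.0
DA,C2',C,-3.564,4.824,0.927
DA,C3',C,-4.226,6.097,1.403
DA,C4',C,-3.072,7.088,1.453
DA,O4',O,-2.134,6.665,0.445
DA,O3',O,-5.449,6.758,1.72
DA,C5',C,-2.349,7.09,2.793
DA,O5',O,-1.607,8.292,2.912
DA,P,P,-1.725,9.139,4.286
DA,OP1,O,-1.718,10.63,4.115
DA,OP2,O,-3.06,8.535,4.969
DC,N1,N,-1.285,4.508,0.0
DC,C2,C,-1.408,3.169,0.0
DC,O2,O,-2.52,2.668,0.0
DC,N3,N,-0.334,2.38,0.0
DC,C4,C,0.887,2.898,0.0
DC,N4,N,1.988,2.074,0.0
DC,C5,C,1.049,4.298,0.0
DC,C6,C,-0.051,5.086,0.0
DC,C1',C,-2.479,5.346,0.0
DC,C2',C,-3.564,4.824,0.927
DC,C3',C,-4.226,6.097,1.403
DC,C4',C,-3.072,7.088,1.453
DC,O4',O,-2.134,6.665,0.445
DC,O3',O,-5.449,6.758,1.72
DC,C5',C,-2.349,7.09,2.793
DC,O5',O,-1.607,8.292,2.912
DC,P,P,-1.725,9.139,4.286
DC,OP1,O,-1.718,10.63,4.115
DC,OP2,O,-3.06,8.535,4.969
DG,N9,N,-1.291,4.498,0.0
DG,C8,C,0.005,4.925,0.0
DG,N7,N,0.807,3.9,0.0
DG,C5,C,0.076,2.758,0.0
DG,C6,C,0.4,1.381,0.0
DG,O6,O,1.562,1.013,0.0
DG,N1,N,-0.611,0.485,0.0
DG,C2,C,-1.906,0.908,0.0
DG,N2,N,-2.911,-0.025,0.0
DG,N3,N,-2.219,2.184,0.0
DG,C4,C,-1.273,3.13,0.0
DG,C1',C,-2.479,5.346,0.0
DG,C2',C,-3.564,4.824,0.927
DG,C3',C,-4.226,6.097,1.403
DG,C4',C,-3.072,7.088,1.453
DG,O4',O,-2.134,6.665,0.445
DG,O3',O,-5.449,6.758,1.72
DG,C5',C,-2.349,7.09,2.793
DG,O5',O,-1.607,8.292,2.912
DG,P,P,-1.725,9.139,4.286
DG,OP1,O,-1.718,10.63,4.115
DG,OP2,O,-3.06,8.535,4.969
DT,N1,N,-1.285,4.508,0.0
DT,C2,C,-1.414,3.103,0.0
DT,O2,O,-2.496,2.513,0.0
DT,N3,N,-0.206,2.397,0.0
DT,C4,C,1.073,2.933,0.0
DT,O4,O,2.095,2.252,0.0
DT,C5,C,1.128,4.419,0.0
DT,C7,C,2.472,5.074,0.0
DT,C6,C,-0.027,5.098,0.0
DT,C1',C,-2.479,5.346,0.0
DT,C2',C,-3.564,4.824,0.927
DT,C3',C,-4.226,6.097,1.403
DT,C4',C,-3.072,7.088,1.453
DT,O4',O,-2.134,6.665,0.445
DT,O3',O,-5.449,6.758,1.72
DT,C5',C,-2.349,7.09,2.793
DT,O5',O,-1.607,8.292,2.912
DT,P,P,-1.725,9.139,4.286
DT,OP1,O,-1.718,10.63,4.115
DT,OP2,O,-3.06,8.535,4.969
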