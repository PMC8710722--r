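name,x,y,region
FP1,-0.25,0.95,F
FPZ,0,0.98,F
FP2,0.25,0.95,F
AF3,-0.35,0.78,F
AF4,0.35,0.78,F
F7,-0.88,0.55,F
F5,-0.65,0.58,F
F3,-0.42,0.6,F
F1,-0.18,0.62,F
FZ,0,0.62,F
F2,0.18,0.62,F
F4,0.42,0.6,F
F6,0.65,0.58,F
F8,0.88,0.55,F
FT7,-0.95,0.28,FC
FC5,-0.7,0.31,FC
FC3,-0.44,0.33,FC
FC1,-0.19,0.34,FC
FCZ,0,0.34,FC
FC2,0.19,0.34,FC
FC4,0.44,0.33,FC
FC6,0.7,0.31,FC
FT8,0.95,0.28,FC
T7,-1,0,C
C5,-0.75,0,C
C3,-0.48,0,C
C1,-0.2,0,C
CZ,0,0,C
C2,0.2,0,C
C4,0.48,0,C
C6,0.75,0,C
T8,1,0,C
M1,-1.15,-0.25,M
TP7,-0.95,-0.28,CP
CP5,-0.7,-0.31,CP
CP3,-0.44,-0.33,CP
CP1,-0.19,-0.34,CP
CPZ,0,-0.34,CP
CP2,0.19,-0.34,CP
CP4,0.44,-0.33,CP
CP6,0.7,-0.31,CP
TP8,0.95,-0.28,CP
M2,1.15,-0.25,M
P7,-0.88,-0.55,P
P5,-0.65,-0.58,P
P3,-0.42,-0.6,P
P1,-0.18,-0.62,P
PZ,0,-0.62,P
P2,0.18,-0.62,P
P4,0.42,-0.6,P
P6,0.65,-0.58,P
P8,0.88,-0.55,P
PO7,-0.75,-0.75,PO
PO5,-0.55,-0.78,PO
PO3,-0.33,-0.8,PO
POZ,0,-0.81,PO
PO4,0.33,-0.8,PO
PO6,0.55,-0.78,PO
PO8,0.75,-0.75,PO
CB1,-0.42,-1.02,O
O1,-0.25,-0.95,O
OZ,0,-0.97,O
O2,0.25,-0.95,O
CB2,0.42,-1.02,O
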