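F5	FC5,F3
F3	F5,FC3,F1
F1	F3,FC1,Fz
Fz	F1,FCz,F2
F2	Fz,FC2,F4
F4	F2,FC4,F6
F6	F4,FC6
FC5	F5,C5,FC3
FC3	FC5,F3,C3,FC1
FC1	FC3,F1,C1,FCz
FCz	FC1,Fz,Cz,FC2
FC2	FCz,F2,C2,FC4
FC4	FC2,F4,C4,FC6
FC6	FC4,F6,C6
C5	FC5,CP5,C3
C3	C5,FC3,CP3,C1
C1	C3,FC1,CP1,Cz
Cz	C1,FCz,CPz,C2
C2	Cz,FC2,CP2,C4
C4	C2,FC4,CP4,C6
C6	C4,FC6,CP6
CP5	C5,P5,CP3
CP3	CP5,C3,P3,CP1
CP1	CP3,C1,P1,CPz
CPz	CP1,Cz,Pz,CP2
CP2	CPz,C2,P2,CP4
CP4	CP2,C4,P4,CP6
CP6	CP4,C6,P6
P5	CP5,P3
P3	P5,CP3,P1
P1	P3,CP1,Pz
Pz	P1,CPz,P2
P2	Pz,CP2,P4
P4	P2,CP4,P6
P6	P4,CP6
PO3	P5,P3,P1,POz
POz	Pz,PO3,PO4
PO4	P2,P4,P6,POz
Oz	POz,PO3,PO4
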