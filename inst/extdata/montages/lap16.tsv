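FC3	FC5,F3,C3,FC1
FCz	FC1,Fz,Cz,FC2
FC4	FC2,F4,C4,FC6
C5	FC5,CP5,C3
C3	C5,FC3,CP3,C1
C1	C3,FC1,CP1,Cz
Cz	C1,FCz,CPz,C2
C2	Cz,FC2,CP2,C4
C4	C2,FC4,CP4,C6
C6	C4,FC6,CP6
CP3	CP5,C3,P3,CP1
CPz	CP1,Cz,Pz,CP2
CP4	CP2,C4,P4,CP6
P3	P5,CP3,P1
Pz	P1,CPz,P2
P4	P2,CP4,P6
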