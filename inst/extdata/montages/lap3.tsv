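C3	C5,FC3,CP3,C1
Cz	C1,FCz,CPz,C2
C4	C2,FC4,CP4,C6
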