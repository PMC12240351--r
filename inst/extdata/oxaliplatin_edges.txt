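# Oxaliplatin heavy-atom skeleton (Pt + oxalate + 1,2-diaminocyclohexane)
Pt O1
Pt O2
Pt N1
Pt N2
O1 C1
C1 C2
C2 O2
C1 O3
C2 O4
N1 C3
N2 C4
C3 C4
C3 C5
C5 C6
C6 C7
C7 C8
C8 C4
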