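subject,group,q_a,q_b,q_c
A1,A,2.8,3,1
A2,A,3,3,2
A3,A,3,3,2
A4,A,1.8,2.6,1
B2,B,3,2.6,2.6
B3,B,3,2.8,2.8
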