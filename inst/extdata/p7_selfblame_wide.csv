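participant,phase,t1,t2,t3,t4,t5,t6
P7,A,4.77,4.78,2.96,4.79,3.99,4.00
P7,B,3.18,2.78,2.99,2.79,2.79,2.20
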