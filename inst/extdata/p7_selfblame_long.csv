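participant,phase,time,value
P7,A,1,4.77
P7,A,2,4.78
P7,A,3,2.96
P7,A,4,4.79
P7,A,5,3.99
P7,A,6,4.00
P7,B,7,3.18
P7,B,8,2.78
P7,B,9,2.99
P7,B,10,2.79
P7,B,11,2.79
P7,B,12,2.20
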