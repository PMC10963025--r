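experiment,train,condition,s1_4AP,s2_4AP,s3_4AP,s4_4AP,s5_4AP,s6_4AP,s7_4AP,s8_4AP,notes
syn01,1,4AP,3,0,4,2,2,1,1,2,
syn01,2,4AP,3,2,3,0,3,1,2,0,
syn01,3,4AP,4,4,1,2,2,1,2,0,
syn01,4,4AP,3,3,3,1,3,2,1,0,
syn01,5,4AP,2,1,2,0,1,2,2,2,
syn01,6,4AP,4,1,3,2,1,1,1,2,
syn01,7,4AP,2,4,2,1,2,1,1,0,
syn01,8,4AP,3,2,2,1,2,2,2,3,
syn01,9,4AP,4,4,0,0,0,1,1,1,
syn01,10,4AP,4,2,2,1,0,1,2,3,
syn01,11,4AP,2,2,3,2,0,1,1,1,
syn01,12,4AP,4,2,2,1,1,1,1,1,
syn01,13,4AP,3,3,1,3,0,1,2,0,
syn01,14,4AP,3,3,3,3,0,1,2,2,
syn01,15,4AP,2,4,1,2,1,1,1,2,
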