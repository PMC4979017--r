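sample,f1,f2,f3,label
v1,1,0.5,-1,CASE
v2,2,1.5,0,CASE
v3,1.5,1,1,CASE
v4,-1,0,1,CONTROL
v5,-2,-0.5,0,CONTROL
v6,-1.5,-1,-1,CONTROL
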