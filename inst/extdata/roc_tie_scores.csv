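score,truth
2,CASE
1,CASE
1,CASE
0,CASE
1,CONTROL
0,CONTROL
-1,CONTROL
-1,CONTROL
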