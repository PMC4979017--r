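probe,stability
m1,0.103760511438
m2,0.262627997031
m3,0.162123415407
m4,0.075834448438
m5,0.415454346450
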