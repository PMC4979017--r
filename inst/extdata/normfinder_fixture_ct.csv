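sample,probe,ct
s01,m1,20.843
s01,m2,22.855
s01,m3,24.936
s01,m4,21.575
s01,m5,23.814
s02,m1,20.777
s02,m2,23.335
s02,m3,25.460
s02,m4,22.443
s02,m5,24.332
s03,m1,20.746
s03,m2,23.313
s03,m3,24.821
s03,m4,21.679
s03,m5,24.102
s04,m1,20.969
s04,m2,22.407
s04,m3,24.839
s04,m4,22.025
s04,m5,24.093
s05,m1,20.760
s05,m2,23.069
s05,m3,25.130
s05,m4,21.959
s05,m5,24.551
s06,m1,21.600
s06,m2,23.642
s06,m3,25.693
s06,m4,22.575
s06,m5,24.990
s07,m1,21.772
s07,m2,24.049
s07,m3,26.210
s07,m4,22.903
s07,m5,25.975
s08,m1,20.496
s08,m2,22.702
s08,m3,24.830
s08,m4,22.107
s08,m5,24.670
s09,m1,20.781
s09,m2,22.259
s09,m3,24.272
s09,m4,21.788
s09,m5,25.152
s10,m1,21.084
s10,m2,23.311
s10,m3,25.433
s10,m4,22.531
s10,m5,26.006
s11,m1,21.974
s11,m2,23.307
s11,m3,25.537
s11,m4,22.529
s11,m5,25.820
s12,m1,21.604
s12,m2,22.829
s12,m3,25.656
s12,m4,22.565
s12,m5,25.363
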