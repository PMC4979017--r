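sample_id,group,cohort,stage,histology,is_calibrator
s01,CONTROL,TRAINING,,,false
s02,CONTROL,TRAINING,,,false
s03,CONTROL,TRAINING,,,false
s04,CONTROL,TRAINING,,,false
s05,CONTROL,TRAINING,,,false
s06,CONTROL,TRAINING,,,false
s07,CASE,TRAINING,,,false
s08,CASE,TRAINING,,,false
s09,CASE,TRAINING,,,false
s10,CASE,TRAINING,,,false
s11,CASE,TRAINING,,,false
s12,CASE,TRAINING,,,false
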