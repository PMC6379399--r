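variable,mean,sd
age,61.08,12.70
roi_liver_L,1.727,0.398
roi_lesion_L,1.015,0.355
ratio,0.5888,0.1535
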