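patient_id,sex,age,roi_liver_L,roi_lesion_L,ratio
Case 1,F,69,1.306,0.833,0.6378
Case 2,F,44,1.166,0.498,0.4271
Case 3,M,74,1.342,0.949,0.7072
Case 4,F,70,1.289,0.956,0.7417
Case 5,F,80,2.081,0.798,0.3835
Case 6,F,58,1.921,1.426,0.7423
Case 7,F,59,1.545,0.538,0.3482
Case 8,M,71,2.069,1.453,0.7023
Case 9,M,50,2.136,1.300,0.6086
Case 10,F,43,1.950,0.999,0.5123
Case 11,F,66,1.857,0.739,0.3980
Case 12,F,67,1.032,0.671,0.6502
Case 13,M,42,1.584,1.015,0.6408
Case 14,M,73,1.413,0.762,0.5393
Case 15,M,74,2.200,1.412,0.6418
Case 16,M,65,1.850,1.295,0.7000
Case 17,M,47,1.808,1.518,0.8396
Case 18,F,66,1.389,1.021,0.7351
Case 19,M,49,2.335,1.650,0.7066
Case 20,M,29,2.617,1.476,0.5640
Case 21,F,62,1.769,1.052,0.5947
Case 22,M,66,1.722,1.242,0.7213
Case 23,F,70,1.976,0.545,0.2758
Case 24,M,71,1.281,0.767,0.5988
Case 25,F,62,1.534,0.465,0.3031
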