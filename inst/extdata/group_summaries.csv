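table,variable,group,n,mean,sd,printed_F,printed_P,consistent
severity,roi_liver_L,mild,6,1.824,0.232,0.357,>0.05,TRUE
severity,roi_liver_L,moderate,10,1.743,0.552,0.357,>0.05,TRUE
severity,roi_liver_L,severe,9,1.645,0.289,0.357,>0.05,TRUE
severity,roi_lesion_L,mild,6,0.681,0.202,4.986,<0.05,FALSE
severity,roi_lesion_L,moderate,10,1.067,0.381,4.986,<0.05,FALSE
severity,roi_lesion_L,severe,9,1.015,0.355,4.986,<0.05,FALSE
severity,ratio,mild,6,0.3701,0.0837,35.638,<0.05,TRUE
severity,ratio,moderate,10,0.6070,0.0742,35.638,<0.05,TRUE
severity,ratio,severe,9,0.7143,0.0781,35.638,<0.05,TRUE
severity_labs,alt,mild,6,42.50,33.71,5.239,<0.05,TRUE
severity_labs,alt,moderate,10,58.20,35.98,5.239,<0.05,TRUE
severity_labs,alt,severe,9,194.67,169.44,5.239,<0.05,TRUE
severity_labs,ast,mild,6,58.33,35.86,7.337,<0.05,TRUE
severity_labs,ast,moderate,10,91.40,47.01,7.337,<0.05,TRUE
severity_labs,ast,severe,9,291.67,215.17,7.337,<0.05,TRUE
severity_labs,alp,mild,6,124.17,31.13,0.742,>0.05,TRUE
severity_labs,alp,moderate,10,165.40,93.10,0.742,>0.05,TRUE
severity_labs,alp,severe,9,158.56,47.51,0.742,>0.05,TRUE
severity_labs,ggt,mild,6,92.33,38.91,1.011,>0.05,TRUE
severity_labs,ggt,moderate,10,160.50,135.75,1.011,>0.05,TRUE
severity_labs,ggt,severe,9,147.44,56.93,1.011,>0.05,TRUE
severity_labs,total_bilirubin,mild,6,19.93,10.54,9.033,<0.05,TRUE
severity_labs,total_bilirubin,moderate,10,43.23,14.49,9.033,<0.05,TRUE
severity_labs,total_bilirubin,severe,9,76.06,38.98,9.033,<0.05,TRUE
severity_labs,albumin,mild,6,34.35,5.45,0.217,>0.05,TRUE
severity_labs,albumin,moderate,10,34.52,3.44,0.217,>0.05,TRUE
severity_labs,albumin,severe,9,33.23,4.84,0.217,>0.05,TRUE
outcome,roi_liver_L,recovery,10,1.938,0.403,2.738,>0.05,TRUE
outcome,roi_liver_L,cirrhosis,9,1.558,0.364,2.738,>0.05,TRUE
outcome,roi_liver_L,death,6,1.629,0.322,2.738,>0.05,TRUE
outcome,roi_lesion_L,recovery,10,0.939,0.428,0.683,>0.05,TRUE
outcome,roi_lesion_L,cirrhosis,9,1.006,0.300,0.683,>0.05,TRUE
outcome,roi_lesion_L,death,6,1.156,0.309,0.683,>0.05,TRUE
outcome,ratio,recovery,10,0.4732,0.1512,8.000,<0.05,FALSE
outcome,ratio,cirrhosis,9,0.6398,0.0322,8.000,<0.05,FALSE
outcome,ratio,death,6,0.7050,0.0969,8.000,<0.05,FALSE
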