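measurand,cvi,cvg,ii
APTT,2.8,7.2,0.39
ALT,11.4,35.2,0.32
AST,2.5,4.1,0.61
ALP,6.0,21.0,0.29
Bilirubin total,20.2,24.6,0.82
Chloride,1.0,1.3,0.77
Cholesterol total,5.2,15.3,0.34
Creatinine,4.4,16.2,0.27
RBC,2.8,7.0,0.40
Glucose,4.6,8.1,0.57
Hematocrit,2.8,5.6,0.50
Hemoglobin,2.7,6.2,0.44
MCV,0.8,3.9,0.21
Potassium,3.9,5.3,0.74
PSA,6.8,42.0,0.16
Protein total,2.6,3.5,0.74
PT,2.6,5.1,0.51
Sodium,0.5,0.7,0.71
TSH,17.9,36.1,0.50
Urea,13.3,20.6,0.65
WBC,11.1,17.2,0.65
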