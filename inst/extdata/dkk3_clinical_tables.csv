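variable,level,level_order,positive,negative,variant,published_p
sex,Male,1,22,42,yates,0.185
sex,Female,2,1,10,yates,0.185
age,<=50,1,9,18,pearson,0.853
age,>50,2,15,33,pearson,0.853
maximal_tumor_size,<=5cm,1,19,29,pearson,0.060
maximal_tumor_size,>5cm,2,5,22,pearson,0.060
liver_cirrhosis,Absent,1,12,33,pearson,0.534
liver_cirrhosis,Present,2,10,20,pearson,0.534
venous_invasion,Absent,1,19,47,yates,0.217
venous_invasion,Present,2,5,4,yates,0.217
tumor_differentiation,I-II,1,3,6,pearson,0.645
tumor_differentiation,II,2,12,31,pearson,0.645
tumor_differentiation,II-III,3,9,14,pearson,0.645
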