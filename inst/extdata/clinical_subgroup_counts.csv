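joint_type,variable,level,accurate,inaccurate
native,alignment,varus,179,14
native,alignment,neutral,38,3
native,alignment,valgus,20,3
native,sex,male,50,8
native,sex,female,187,12
native,bmi,le_25,68,5
native,bmi,gt_25,166,18
native,age,le_60,52,5
native,age,gt_60,187,12
prosthesis,alignment,varus,72,6
prosthesis,alignment,neutral,47,5
prosthesis,alignment,valgus,9,3
prosthesis,sex,male,30,5
prosthesis,sex,female,98,9
prosthesis,bmi,le_25,32,5
prosthesis,bmi,gt_25,96,9
prosthesis,age,le_60,28,3
prosthesis,age,gt_60,100,11
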