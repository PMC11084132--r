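comparison,group,category,count
training_smoking,lung_cancer,current,7
training_smoking,lung_cancer,ex,20
training_smoking,lung_cancer,never,43
training_smoking,control,current,8
training_smoking,control,ex,3
training_smoking,control,never,37
validation_smoking,lung_cancer,current,1
validation_smoking,lung_cancer,ex,6
validation_smoking,lung_cancer,never,13
validation_smoking,control,current,4
validation_smoking,control,ex,4
validation_smoking,control,never,22
test_smoking,lung_cancer,current,7
test_smoking,lung_cancer,ex,8
test_smoking,lung_cancer,never,13
test_smoking,control,current,6
test_smoking,control,ex,6
test_smoking,control,never,23
training_vs_validation_smoking,training,current,15
training_vs_validation_smoking,training,ex,23
training_vs_validation_smoking,training,never,80
training_vs_validation_smoking,validation,current,5
training_vs_validation_smoking,validation,ex,10
training_vs_validation_smoking,validation,never,35
training_sex,lung_cancer,male,39
training_sex,lung_cancer,female,31
training_sex,control,male,19
training_sex,control,female,29
validation_sex,lung_cancer,male,8
validation_sex,lung_cancer,female,12
validation_sex,control,male,18
validation_sex,control,female,12
test_sex,lung_cancer,male,18
test_sex,lung_cancer,female,10
test_sex,control,male,15
test_sex,control,female,20
training_vs_validation_sex,training,male,58
training_vs_validation_sex,training,female,60
training_vs_validation_sex,validation,male,26
training_vs_validation_sex,validation,female,24
training_dm,lung_cancer,dm,8
training_dm,lung_cancer,no_dm,62
training_dm,control,dm,5
training_dm,control,no_dm,43
validation_dm,lung_cancer,dm,3
validation_dm,lung_cancer,no_dm,17
validation_dm,control,dm,4
validation_dm,control,no_dm,26
test_dm,lung_cancer,dm,6
test_dm,lung_cancer,no_dm,22
test_dm,control,dm,4
test_dm,control,no_dm,31
training_copd,lung_cancer,copd,8
training_copd,lung_cancer,no_copd,62
training_copd,control,copd,5
training_copd,control,no_copd,43
validation_copd,lung_cancer,copd,2
validation_copd,lung_cancer,no_copd,18
validation_copd,control,copd,10
validation_copd,control,no_copd,20
test_copd,lung_cancer,copd,7
test_copd,lung_cancer,no_copd,21
test_copd,control,copd,9
test_copd,control,no_copd,26
training_vs_validation_copd,training,copd,13
training_vs_validation_copd,training,no_copd,105
training_vs_validation_copd,validation,copd,12
training_vs_validation_copd,validation,no_copd,38
training_htn,lung_cancer,htn,24
training_htn,lung_cancer,no_htn,46
training_htn,control,htn,13
training_htn,control,no_htn,35
validation_htn,lung_cancer,htn,7
validation_htn,lung_cancer,no_htn,13
validation_htn,control,htn,7
validation_htn,control,no_htn,23
test_htn,lung_cancer,htn,5
test_htn,lung_cancer,no_htn,23
test_htn,control,htn,5
test_htn,control,no_htn,30
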