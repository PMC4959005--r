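cohort,diabetes_group,domain,baseline_age,dfy,dy,lyl,onset_age
1,diabetes,mobility,50,13.0,4.2,2.8,63.0
1,diabetes,mobility,60,6.8,1.6,1.6,66.8
1,diabetes,iadl,50,13.5,3.7,2.8,63.5
1,diabetes,iadl,60,6.9,1.6,1.6,66.9
1,diabetes,adl,50,12.7,4.5,2.8,62.7
1,diabetes,adl,60,6.4,2.0,1.6,66.4
1,no_diabetes,mobility,50,17.0,1.8,1.2,67.0
1,no_diabetes,mobility,60,8.6,0.7,0.7,68.6
1,no_diabetes,iadl,50,16.9,1.9,1.2,66.9
1,no_diabetes,iadl,60,8.5,0.8,0.7,68.5
1,no_diabetes,adl,50,16.4,2.4,1.2,66.4
1,no_diabetes,adl,60,8.3,1.0,0.7,68.3
2,diabetes,mobility,50,14.8,3.6,1.5,64.8
2,diabetes,mobility,60,7.9,0.9,1.3,67.9
2,diabetes,iadl,50,14.3,4.1,1.5,64.3
2,diabetes,iadl,60,7.8,0.9,1.3,67.8
2,diabetes,adl,50,15.0,3.5,1.5,65.0
2,diabetes,adl,60,7.8,0.9,1.3,67.8
2,no_diabetes,mobility,50,17.9,1.5,0.6,67.9
2,no_diabetes,mobility,60,9.1,0.4,0.5,69.1
2,no_diabetes,iadl,50,17.4,2.0,0.6,67.4
2,no_diabetes,iadl,60,9.1,0.4,0.5,69.1
2,no_diabetes,adl,50,17.6,1.8,0.6,67.6
2,no_diabetes,adl,60,9.0,0.5,0.5,69.0
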