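cohort,diabetes_group,domain,baseline_age,dfy,dy,lyl,onset_age
1,diabetes,mobility,50,11.3,6.8,1.9,61.3
1,diabetes,mobility,60,6.2,2.7,1.1,66.2
1,diabetes,iadl,50,13.0,5.1,1.9,63.0
1,diabetes,iadl,60,6.8,2.2,1.1,66.8
1,diabetes,adl,50,12.3,5.8,1.9,62.3
1,diabetes,adl,60,6.3,2.6,1.1,66.3
1,no_diabetes,mobility,50,16.1,3.1,0.8,66.1
1,no_diabetes,mobility,60,8.4,1.2,0.4,68.4
1,no_diabetes,iadl,50,16.6,2.6,0.8,66.6
1,no_diabetes,iadl,60,8.5,1.1,0.4,68.5
1,no_diabetes,adl,50,16.2,3.1,0.8,66.2
1,no_diabetes,adl,60,8.2,1.3,0.4,68.2
2,diabetes,mobility,50,13.2,5.7,1.1,63.2
2,diabetes,mobility,60,7.6,1.4,0.9,67.6
2,diabetes,iadl,50,14.1,4.8,1.1,64.1
2,diabetes,iadl,60,8.0,1.1,0.9,68.0
2,diabetes,adl,50,14.6,4.3,1.1,64.6
2,diabetes,adl,60,7.9,1.2,0.9,67.9
2,no_diabetes,mobility,50,17.2,2.4,0.4,67.2
2,no_diabetes,mobility,60,9.1,0.6,0.4,69.1
2,no_diabetes,iadl,50,17.2,2.3,0.4,67.2
2,no_diabetes,iadl,60,9.1,0.5,0.4,69.1
2,no_diabetes,adl,50,17.4,2.2,0.4,67.4
2,no_diabetes,adl,60,9.1,0.6,0.4,69.1
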