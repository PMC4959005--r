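diabetes_group,measure,domain,band,cohort1,cohort2
diabetes,onset,mobility,50-60,6.7,4.7
diabetes,onset,mobility,61-70,7.0,3.5
diabetes,onset,mobility,total,6.7,3.9
diabetes,onset,iadl,50-60,5.7,4.3
diabetes,onset,iadl,61-70,6.3,2.9
diabetes,onset,iadl,total,5.9,3.5
diabetes,onset,adl,50-60,6.8,4.4
diabetes,onset,adl,61-70,7.9,3.2
diabetes,onset,adl,total,7.0,3.7
diabetes,recover,mobility,50-60,18.4,23.9
diabetes,recover,mobility,61-70,15.6,23.5
diabetes,recover,mobility,total,15.9,23.5
diabetes,recover,iadl,50-60,15.3,26.3
diabetes,recover,iadl,61-70,17.3,26.7
diabetes,recover,iadl,total,17.3,26.6
diabetes,recover,adl,50-60,12.4,24.4
diabetes,recover,adl,61-70,15.8,26.1
diabetes,recover,adl,total,15.7,25.7
diabetes,die_dis,mobility,50-60,2.9,1.4
diabetes,die_dis,mobility,61-70,5.8,5.3
diabetes,die_dis,mobility,total,4.5,4.1
diabetes,die_dis,iadl,50-60,3.0,1.9
diabetes,die_dis,iadl,61-70,5.4,4.3
diabetes,die_dis,iadl,total,4.4,3.5
diabetes,die_dis,adl,50-60,2.4,1.1
diabetes,die_dis,adl,61-70,5.7,5.3
diabetes,die_dis,adl,total,4.3,3.9
no_diabetes,onset,mobility,50-60,2.0,1.5
no_diabetes,onset,mobility,61-70,2.6,1.2
no_diabetes,onset,mobility,total,2.2,1.4
no_diabetes,onset,iadl,50-60,2.0,1.5
no_diabetes,onset,iadl,61-70,2.6,1.4
no_diabetes,onset,iadl,total,2.3,1.4
no_diabetes,onset,adl,50-60,2.4,1.7
no_diabetes,onset,adl,61-70,3.3,1.5
no_diabetes,onset,adl,total,2.8,1.6
no_diabetes,recover,mobility,50-60,18.8,26.4
no_diabetes,recover,mobility,61-70,21.0,26.3
no_diabetes,recover,mobility,total,20.8,26.3
no_diabetes,recover,iadl,50-60,21.8,29.4
no_diabetes,recover,iadl,61-70,21.9,30.9
no_diabetes,recover,iadl,total,21.9,30.8
no_diabetes,recover,adl,50-60,21.5,29.7
no_diabetes,recover,adl,61-70,23.2,30.9
no_diabetes,recover,adl,total,22.8,30.6
no_diabetes,die_dis,mobility,50-60,1.3,1.6
no_diabetes,die_dis,mobility,61-70,3.9,3.9
no_diabetes,die_dis,mobility,total,2.9,3.2
no_diabetes,die_dis,iadl,50-60,1.1,0.4
no_diabetes,die_dis,iadl,61-70,3.8,3.8
no_diabetes,die_dis,iadl,total,3.0,2.6
no_diabetes,die_dis,adl,50-60,1.0,1.5
no_diabetes,die_dis,adl,61-70,3.1,3.0
no_diabetes,die_dis,adl,total,2.4,2.5
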