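diabetes_group,obesity_class,cohort1_pct,cohort2_pct
diabetes,II,10.7,18.5
diabetes,III,6.4,14.3
no_diabetes,II,3.5,7.7
no_diabetes,III,1.6,3.7
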