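statistic,kind,baseline_all,reexam,baseline_only,substitution,extrapolation
"Smoking: yes, regularly",prevalence_percent,23,22,29,27,34
"Smoking: yes, occasionally",prevalence_percent,4.5,4.4,4.6,4.6,4.8
"Smoking: no, stopped",prevalence_percent,34,34,33,33,32
"Smoking: no, never",prevalence_percent,39,40,33,35,29
Alcohol: high risk,prevalence_percent,8.0,7.8,9.2,8.7,10
Body mass: normal or underweight,prevalence_percent,47,48,45,46,43
Body mass: overweight,prevalence_percent,40,40,40,40,40
Body mass: obese,prevalence_percent,13,13,16,15,17
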