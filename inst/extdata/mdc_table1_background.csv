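statistic,kind,population,nonparticipant,baseline_all,reexam,baseline_only,substitution,extrapolation
Age: 50-59,prevalence_percent,36,38,33,31,39,36,43
Age: 60-69,prevalence_percent,37,36,37,37,36,36,35
Age: 70-77,prevalence_percent,28,26,30,31,26,27,22
Legal sex: male,prevalence_percent,40,41,38,38,38,38,38
Country of birth: Sweden,prevalence_percent,79,73,88,89,83,85,80
Civil status: married,prevalence_percent,55,52,61,62,55,57,50
Education: primary,prevalence_percent,42,46,36,35,38,37,39
Education: short secondary,prevalence_percent,28,26,30,30,30,30,30
Education: long secondary,prevalence_percent,11,10,13,13,12,12,12
Education: tertiary,prevalence_percent,19,17,22,22,20,21,19
Employment: employed,prevalence_percent,33,31,36,36,37,37,38
Employment: unemployed,prevalence_percent,8.6,10,5.8,5.6,7.0,6.5,7.9
Employment: sickness absence,prevalence_percent,3.5,3.9,2.8,2.5,4.0,3.5,4.9
Employment: retired,prevalence_percent,54,54,55,56,52,53,50
Disposable income: quintile 1,prevalence_percent,20,23,16,16,17,16,17
Disposable income: quintile 2,prevalence_percent,20,22,17,17,19,18,20
Disposable income: quintile 3,prevalence_percent,20,20,20,20,21,20,21
Disposable income: quintile 4,prevalence_percent,20,18,23,24,22,23,21
Disposable income: quintile 5,prevalence_percent,20,17,24,25,22,23,20
Disease history: circulatory,prevalence_percent,16,17,16,16,17,16,18
Disease history: diabetes,prevalence_percent,1.8,2.2,1.2,1.2,1.5,1.4,1.7
Disease history: neoplasms,prevalence_percent,10,9.6,11,11,11,11,11
Disease history: respiratory,prevalence_percent,5.7,6.1,5.1,5.0,5.9,5.6,6.5
Disease history: digestive,prevalence_percent,13,12,13,13,15,14,16
Disease history: mental,prevalence_percent,5.4,7.0,3.1,2.6,5.4,4.5,7.2
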