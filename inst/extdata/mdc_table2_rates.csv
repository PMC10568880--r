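statistic,kind,population,nonparticipant,baseline_all,reexam,baseline_only,substitution,extrapolation
All-cause mortality,rate_per_10k_py,284,318,237,232,260,251,276
CVD mortality,rate_per_10k_py,97,110,78,75,91,86,100
Cancer mortality,rate_per_10k_py,88,93,80,80,79,79,78
Smoking-related mortality,rate_per_10k_py,33,39,24,24,28,27,31
Alcohol-related mortality,rate_per_10k_py,2.6,3.4,1.5,1.2,2.7,2.2,3.6
CVD incidence,rate_per_10k_py,178,191,158,155,174,167,184
Cancer incidence,rate_per_10k_py,284,279,291,296,266,276,248
Smoking-related incidence,rate_per_10k_py,76,89,59,57,70,66,78
Alcohol-related incidence,rate_per_10k_py,25,32,15,13,24,20,30
Mean follow-up,mean_followup_years,12.68,,13.25,13.33,,,
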