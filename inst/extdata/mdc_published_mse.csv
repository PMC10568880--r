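table,column,mse
1,baseline_all,10.7
1,reexam,13.6
1,baseline_only,4.4
1,substitution,5.4
1,extrapolation,8.4
2,baseline_all,380
2,reexam,482
2,baseline_only,114
2,substitution,178
2,extrapolation,167
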