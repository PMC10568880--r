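group,n
population,65068
nonparticipant,38594
baseline_all,26474
reexam,21868
baseline_only,4606
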