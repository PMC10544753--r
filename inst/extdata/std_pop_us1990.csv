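age_group,proportion
20_34,0.378654
35_49,0.313261
50_64,0.197882
65_plus,0.110204
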