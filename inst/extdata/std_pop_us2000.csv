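age_group,proportion
20_34,0.202052
35_49,0.234731
50_64,0.149963
65_plus,0.066037
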