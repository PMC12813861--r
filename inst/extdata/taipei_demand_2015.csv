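# Taipei yearly EAS demand in the 2015 base year by age band and sex
# (records with missing age or sex excluded)
age_band,sex,count
0-64,male,49554
0-64,female,32703
0-64,both,82361
65-74,male,7366
65-74,female,5441
65-74,both,12815
75-84,male,8029
75-84,female,7373
75-84,both,15409
85+,male,9387
85+,female,7826
85+,both,17218
ALL,male,74336
ALL,female,53343
ALL,both,127803
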