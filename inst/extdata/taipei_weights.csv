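# Taipei age-gender-specific population-change weighting factors, base year 2015
base_year,target_year,age_band,sex,weight
2015,2036,0-64,male,0.86
2015,2036,0-64,female,0.81
2015,2036,0-64,both,0.84
2015,2036,65-74,male,1.66
2015,2036,65-74,female,1.72
2015,2036,65-74,both,1.69
2015,2036,75-84,male,2.61
2015,2036,75-84,female,2.69
2015,2036,75-84,both,2.66
2015,2036,85+,male,2.22
2015,2036,85+,female,4.63
2015,2036,85+,both,3.43
2015,2036,ALL,male,1.02
2015,2036,ALL,female,1.06
2015,2036,ALL,both,1.04
2015,2051,0-64,male,0.76
2015,2051,0-64,female,0.66
2015,2051,0-64,both,0.71
2015,2051,65-74,male,1.77
2015,2051,65-74,female,1.78
2015,2051,65-74,both,1.78
2015,2051,75-84,male,2.77
2015,2051,75-84,female,2.91
2015,2051,75-84,both,2.85
2015,2051,85+,male,4.20
2015,2051,85+,female,10.13
2015,2051,85+,both,7.18
2015,2051,ALL,male,0.99
2015,2051,ALL,female,1.05
2015,2051,ALL,both,1.02
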