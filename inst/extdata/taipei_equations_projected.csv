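# Taipei reference projected temperature-demand equations for 2036 and 2051,
# with and without age-gender structure adjustment. ALL/both rows are the
# coefficient-wise sums of the eight stratum equations of that block.
year,adjustment,sex,age_band,constant,b1,b2
2036,with,male,0-64,132.21,-1.62,0.04
2036,with,male,65-74,42.64,-0.61,0.01
2036,with,male,75-84,78.90,-1.44,0.02
2036,with,male,85+,100.19,-3.30,0.06
2036,with,female,0-64,74.42,-0.08,0.00
2036,with,female,65-74,32.20,-0.45,0.01
2036,with,female,75-84,80.43,-1.75,0.03
2036,with,female,85+,204.83,-7.82,0.13
2036,with,both,ALL,745.82,-17.07,0.30
2036,without,male,0-64,159.52,-1.96,0.05
2036,without,male,65-74,26.73,-0.38,0.01
2036,without,male,75-84,31.47,-0.57,0.01
2036,without,male,85+,46.95,-1.54,0.03
2036,without,female,0-64,95.38,-0.10,0.00
2036,without,female,65-74,19.48,-0.27,0.00
2036,without,female,75-84,31.08,-0.68,0.01
2036,without,female,85+,46.04,-1.76,0.03
2036,without,both,ALL,456.64,-7.27,0.14
2051,with,male,0-64,116.28,-1.43,0.03
2051,with,male,65-74,45.43,-0.65,0.01
2051,with,male,75-84,83.84,-1.53,0.02
2051,with,male,85+,189.62,-6.24,0.11
2051,with,female,0-64,60.38,-0.07,0.00
2051,with,female,65-74,33.40,-0.46,0.01
2051,with,female,75-84,87.04,-1.90,0.03
2051,with,female,85+,448.17,-17.11,0.29
2051,with,both,ALL,1064,-29.38,0.51
2051,without,male,0-64,156.56,-1.92,0.05
2051,without,male,65-74,26.24,-0.38,0.01
2051,without,male,75-84,30.88,-0.56,0.01
2051,without,male,85+,46.08,-1.52,0.03
2051,without,female,0-64,93.61,-0.10,0.00
2051,without,female,65-74,19.12,-0.26,0.00
2051,without,female,75-84,30.51,-0.66,0.01
2051,without,female,85+,45.19,-1.72,0.03
2051,without,both,ALL,448.19,-7.13,0.13
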