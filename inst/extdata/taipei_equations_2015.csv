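# Taipei base-year (2015) quadratic temperature-demand equations per stratum:
# demand/day = constant + b1*T + b2*T^2, T = daily mean temperature (degC).
# The ALL/both row is the coefficient-wise sum of the eight stratum equations.
sex,age_band,constant,b1,b2,ci_b1_low,ci_b1_high,ci_b2_low,ci_b2_high,adj_r2
male,0-64,153.31,-1.88,0.05,-3.82,0.05,0.00,0.09,0.02
male,65-74,25.69,-0.37,0.01,-0.94,0.20,-0.01,0.02,0.04
male,75-84,30.24,-0.55,0.01,-1.18,0.07,-0.01,0.02,0.07
male,85+,45.12,-1.48,0.03,-2.26,-0.71,0.01,0.04,0.12
female,0-64,91.67,-0.10,0.00,-1.41,1.21,-0.03,0.03,0.00
female,65-74,18.72,-0.26,0.00,-0.67,0.16,-0.01,0.01,0.03
female,75-84,29.87,-0.65,0.01,-1.20,-0.10,-0.00,0.02,0.12
female,85+,44.25,-1.69,0.03,-2.34,-1.04,0.02,0.04,0.24
both,ALL,438.87,-6.99,0.13,NA,NA,NA,NA,NA
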