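# Taipei reference EAS demand projections for 2036 and 2051 (base year 2015):
# actual base-year demand, uniform-ratio (unadjusted) projection,
# age-gender-weighted (adjusted) projection, and the reported integer
# misestimation percentage. The 2051 ALL row is internally inconsistent in
# the source table; its unadjusted/adjusted cells are recomputed from the
# stratum rows (NA here), while the reported percentages are retained.
year,age_band,sex,actual,unadjusted,adjusted,diff_pct
2036,0-64,male,49554,51560,42733,21
2036,0-64,female,32703,34027,26550,28
2036,0-64,both,82361,85695,68875,24
2036,65-74,male,7366,7664,12225,-37
2036,65-74,female,5441,5661,9359,-40
2036,65-74,both,12815,13334,21691,-39
2036,75-84,male,8029,8354,20947,-60
2036,75-84,female,7373,7671,19851,-61
2036,75-84,both,15409,16033,40933,-61
2036,85+,male,9387,9767,20843,-53
2036,85+,female,7826,8143,36229,-78
2036,85+,both,17218,17915,59100,-70
2036,ALL,male,74336,77345,96749,-20
2036,ALL,female,53343,55502,91989,-40
2036,ALL,both,127803,132977,190599,-30
2051,0-64,male,49554,50606,37586,35
2051,0-64,female,32703,33397,21540,55
2051,0-64,both,82361,84110,58221,44
2051,65-74,male,7366,7522,13023,-42
2051,65-74,female,5441,5557,9708,-43
2051,65-74,both,12815,13087,22770,-43
2051,75-84,male,8029,8199,22260,-63
2051,75-84,female,7373,7530,21482,-65
2051,75-84,both,15409,15736,43959,-64
2051,85+,male,9387,9586,39448,-76
2051,85+,female,7826,7992,79269,-90
2051,85+,both,17218,17584,123699,-86
2051,ALL,male,74336,75914,NA,-32
2051,ALL,female,53343,54476,NA,-59
2051,ALL,both,127803,NA,NA,-48
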