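# Published per-gland paired differences (treated eye - control eye) in the
# deformation coefficient, 10 central upper-eyelid glands numbered temporal
# (1) to nasal (10). Columns as printed: mean difference, SD of differences,
# SE of the mean, 95% CI (ascending), t, two-tailed p.
gland_index,mean_diff,sd,se,ci_lo,ci_hi,t,p
1,0.121,0.384,0.064,-0.009,0.251,1.888,0.067
2,0.420,1.016,0.169,0.076,0.764,2.481,0.018
3,1.207,1.544,0.257,0.685,1.730,4.691,0.000
4,2.195,2.919,0.487,1.208,3.183,4.512,0.000
5,4.563,3.536,0.589,3.367,5.759,7.744,0.000
6,4.960,5.345,0.891,3.152,6.769,5.569,0.000
7,2.205,2.062,0.344,1.508,2.903,6.417,0.000
8,0.634,1.165,0.194,0.240,1.028,3.266,0.002
9,0.077,0.439,0.073,-0.072,0.225,1.049,0.301
10,0.268,0.343,0.057,0.151,0.384,4.677,0.000
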