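# Published treated-eye deformation coefficients by gland site (mean, SD and
# printed 95% CI of the mean), 10 central upper-eyelid glands.
gland_index,mean,sd,ci_lo,ci_hi
1,1.983,0.454,1.830,2.137
2,2.179,0.963,1.853,2.505
3,3.285,1.270,2.855,3.714
4,4.120,2.894,3.141,5.099
5,6.608,3.424,5.449,7.767
6,7.447,4.500,5.925,8.970
7,4.176,2.136,3.453,4.899
8,2.684,1.248,2.261,3.106
9,1.852,0.469,1.693,2.011
10,1.890,0.457,1.736,2.045
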