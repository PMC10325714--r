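# Published control-eye deformation coefficients by gland site (mean, SD and
# printed 95% CI of the mean), 10 central upper-eyelid glands.
gland_index,mean,sd,ci_lo,ci_hi
1,1.862,0.404,1.726,1.999
2,1.759,0.335,1.646,1.873
3,2.077,0.426,1.933,2.222
4,1.925,0.447,1.773,2.076
5,2.045,0.411,1.906,2.184
6,2.487,2.328,1.699,3.274
7,1.971,0.275,1.878,2.063
8,2.050,0.437,1.902,2.197
9,1.775,0.359,1.653,1.897
10,1.622,0.284,1.527,1.718
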