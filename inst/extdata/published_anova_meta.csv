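# Printed one-way ANOVA results across the 10 gland sites within each group,
# and the printed Fisher LSD ordering strings.
group,F,p,lsd
treatment,29.003,0.000,"5, 6 > 3, 4 > 1, 2, 8, 9, 10"
control,3.011,0.002,"6 > 1,2,3,4,5,7,8,9,10; 3, 5, 8 > 10"
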