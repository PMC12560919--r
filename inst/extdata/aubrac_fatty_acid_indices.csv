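quantity,male,female,overall
n3,0.44,0.56,0.47
n6,6.51,2.23,5.39
tfa,2.67,2.06,2.51
sfa,49.73,46.82,48.96
mufa,37.21,44.45,39.11
pufa,4.43,2.66,3.96
ufa,41.64,47.11,43.08
ufa_sfa,0.84,1.01,0.88
n6_n3,14.93,4.06,12.07
ai,0.798,0.885,0.821
ti,2.03,1.74,1.54
hfa_upper,25.48,31.71,27.11
hfa_lower,6.38,4.52,5.89
h_over_H,0.250,0.142,0.217
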