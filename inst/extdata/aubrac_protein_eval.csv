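quantity,basis,children,youth,adults
Ile,5.92,128.71,148.01,197.35
Leu,10.31,110.91,147.35,234.42
Lys,11.47,173.80,208.56,370.03
Met+Cys,4.58,109.03,130.83,169.60
Phe+Tyr,9.57,132.98,159.57,290.14
Thr,5.78,134.46,144.54,222.37
Trp,13.88,816.24,1387.60,2312.67
Val,6.06,110.17,121.18,263.44
EAA,67.58,NA,NA,NA
EAAI,NA,160.25,197.43,321.49
BV,NA,162.97,203.50,338.73
NI,NA,34.65,42.68,69.51
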