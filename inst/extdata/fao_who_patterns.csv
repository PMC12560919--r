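group,children,youth,adults
Ile,4.6,4.0,3.0
Leu,9.3,7.0,4.4
Lys,6.6,5.5,3.1
Met+Cys,4.2,3.5,2.7
Phe+Tyr,7.2,6.0,3.3
Thr,4.3,4.0,2.6
Trp,1.7,1.0,0.6
Val,5.5,5.0,2.3
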