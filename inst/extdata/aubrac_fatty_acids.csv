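acid,male_mean,male_sd,female_mean,female_sd,significance,overall_mean,overall_sd
C10:0,0.51,0.09,0.10,0.02,***,0.40,0.20
C12:0,0.50,0.11,0.12,0.02,***,0.40,0.19
C14:0,3.26,0.07,3.36,0.10,**,3.28,0.09
C14:1,0.62,0.11,0.64,0.05,ns,0.63,0.09
C15:0,0.47,0.05,0.50,0.06,ns,0.48,0.05
C16:0,21.72,0.98,28.23,0.74,***,23.43,3.05
C16:1,2.39,0.36,4.38,0.34,***,2.92,0.95
C17:0,1.04,0.07,0.98,0.05,*,1.02,0.07
C18:0,22.15,1.24,13.45,0.61,***,9.86,4.04
C18:1 cis,34.02,1.10,39.31,0.54,***,35.41,2.56
C18:1 trans,1.95,0.17,1.86,0.09,ns,1.93,0.16
C18:2 cis,3.99,0.28,2.10,0.04,***,3.50,0.88
C18:3 cis n3,0.44,0.03,0.56,0.09,***,0.47,0.07
C20:0,0.08,0.14,0.09,0.01,ns,0.09,0.12
C20:1,0.17,0.01,0.12,0.01,***,0.16,0.02
C18:2 trans,2.52,0.28,0.14,0.01,***,1.89,1.09
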