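locus,allele,pct_total,pct_high,pct_low,or,or_upper,p
C,C*14:02:01G,6.94,12.07,3.49,4.24,21.24,0.05
DPB1,DPB1*04:02:01G,11.81,17.24,8.14,2.71,8.57,0.08
DPB1,DPB1*03:01:01G,6.94,1.72,10.47,0.17,0.90,0.10
DQA1,DQA1*05:01:01G,42.36,48.28,38.37,2.17,6.24,0.12
A,A*02:01:01G,31.25,37.93,26.74,1.69,3.59,0.16
C,C*04:01:01G,8.33,12.07,5.81,2.42,9.06,0.17
C,C*07:02:01G,11.11,6.90,13.95,0.50,1.42,0.23
DRB3,DRB3*02:02:01i,22.92,27.59,19.77,1.45,3.06,0.32
DQA1,DQA1*01:02:01G,7.64,5.17,9.30,0.50,1.94,0.35
B,B*07:02:01G,11.81,8.62,13.95,0.62,1.67,0.37
C,C*07:01:01G,27.78,24.14,30.23,0.69,1.57,0.38
DQB1,DQB1*03:01:01i,9.72,12.07,8.14,1.64,5.40,0.41
DPB1,DPB1*01:01:01G,9.72,12.07,8.14,1.52,4.68,0.45
DRB4,DRB4*01:01:01i,9.03,6.90,10.47,0.69,1.99,0.51
DRB1,DRB1*01:01:01i,16.67,18.97,15.12,1.36,3.50,0.52
A,A*11:01:01G,5.56,6.90,4.65,1.56,7.15,0.55
A,A*03:01:01G,16.67,18.97,15.12,1.28,3.03,0.56
B,B*08:01:01G,24.31,22.41,25.58,0.78,1.99,0.60
B,B*51:01:01G,9.03,10.34,8.14,1.34,4.54,0.63
A,A*01:01:01G,24.31,22.41,25.58,0.83,1.87,0.65
DQA1,DQA1*03:01:01G,6.25,5.17,6.98,0.71,2.96,0.65
B,B*35:01:01G,7.64,8.62,6.98,1.28,4.73,0.70
C,C*05:01:01G,9.72,8.62,10.47,0.82,2.44,0.72
DRB3,DRB3*01:01:02i,32.64,31.03,33.72,0.87,1.85,0.72
B,B*44:02:01G,7.64,6.90,8.14,0.85,2.79,0.79
DPB1,DPB1*02:01:02G,14.58,15.52,13.95,1.13,2.82,0.80
DQA1,DQA1*01:01:01G,21.53,20.69,22.09,0.90,2.22,0.82
DRB1,DRB1*13:01:01i,13.19,13.79,12.79,1.11,3.20,0.85
DRB5,DRB5*01:01:01i,5.56,5.17,5.81,0.88,3.89,0.87
B,B*15:01:01G,5.56,5.17,5.81,0.88,3.89,0.87
DQA1,DQA1*01:03:01G,16.67,17.24,16.28,1.08,2.76,0.87
DPB1,DPB1*04:01:01G,36.81,36.21,37.21,0.95,2.03,0.89
DQB1,DQB1*05:01:01i,20.83,20.69,20.93,0.98,2.43,0.97
DQB1,DQB1*06:03:01i,13.89,13.79,13.95,0.98,2.80,0.98
DQB1,DQB1*02:01:01i,36.11,36.21,36.05,1.01,2.61,0.98
C,C*03:03:01G,6.94,6.90,6.98,0.99,3.81,0.98
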