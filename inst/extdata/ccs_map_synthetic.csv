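icd9,ccs_group,kind
191.9,35,dx
198.3,42,dx
170.9,36,dx
189.0,33,dx
194.0,41,dx
201.90,37,dx
202.80,38,dx
204.00,39,dx
204.01,39,dx
205.00,39,dx
239.9,44,dx
238.75,44,dx
V58.11,45,dx
V58.1,45,dx
038.9,2,dx
790.7,3,dx
112.0,4,dx
079.99,7,dx
047.9,76,dx
486,122,dx
487.1,123,dx
465.9,126,dx
008.45,135,dx
599.0,159,dx
682.9,197,dx
780.6,246,dx
780.60,246,dx
785.50,249,dx
785.52,249,dx
999.31,237,dx
996.62,237,dx
996.67,237,dx
996.69,237,dx
996.4,237,dx
996.85,237,dx
285.9,59,dx
285.1,60,dx
287.5,62,dx
288.0,63,dx
288.00,63,dx
288.03,63,dx
284.8,64,dx
284.1,64,dx
276.51,55,dx
276.5,55,dx
276.1,55,dx
780.39,83,dx
331.4,95,dx
427.5,107,dx
518.81,131,dx
799.1,131,dx
577.0,152,dx
578.9,153,dx
584.9,157,dx
998.11,238,dx
787.01,250,dx
789.00,251,dx
780.79,252,dx
995.27,253,dx
V57.89,254,dx
493.92,128,dx
648.91,196,dx
664.01,195,dx
V30.00,218,dx
959.9,244,dx
250.01,49,dx
786.2,133,dx
99.25,224,proc
99.28,224,proc
41.00,64,proc
41.01,64,proc
41.05,64,proc
41.09,64,proc
41.31,67,proc
40.11,66,proc
40.3,66,proc
03.31,9,proc
03.09,3,proc
01.59,1,proc
02.2,2,proc
86.07,61,proc
38.93,61,proc
54.4,89,proc
55.51,99,proc
87.03,177,proc
88.91,177,proc
99.04,222,proc
99.05,222,proc
47.09,80,proc
38.92,63,proc
96.04,216,proc
93.90,216,proc
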