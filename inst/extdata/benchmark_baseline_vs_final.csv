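dataset,week,stage,aar_base,aar_final,delta_aar,mar_base,mar_final,delta_abs_bias
UNCW,0,Early,59.03,83.33,24.30,1.037,0.989,0.026
UNCW,4,Early,28.91,49.17,20.26,1.038,0.964,0.002
UNCW,8,Early/Late,33.96,47.19,13.23,0.959,0.954,-0.005
UNCW,12,Early/Late,41.49,53.56,12.07,0.965,0.955,-0.010
UNCW,18,Late,65.87,75.96,10.09,0.967,0.970,0.003
UNCW,23,Late,84.29,88.48,4.19,0.979,0.980,0.001
Mote,0,Early,5.86,60.13,54.27,1.205,0.995,0.200
Mote,8,Early/Late,75.28,67.93,-7.35,1.026,1.036,-0.010
Mote,15,Late,87.36,93.10,5.74,0.991,0.999,0.008
Mote,21,Late,92.00,95.29,3.29,0.988,0.997,0.009
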