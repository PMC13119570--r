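dataset,week,stage,aar_final,aar_ablation,delta_aar,mar_final,mar_ablation,delta_abs_bias
UNCW,0,Early,83.33,82.64,-0.69,0.989,1.013,-0.002
UNCW,4,Early,49.17,52.96,3.79,0.964,0.995,0.031
UNCW,8,Early/Late,47.19,27.72,-19.47,0.954,0.935,-0.019
UNCW,12,Early/Late,53.56,26.78,-26.78,0.955,0.938,-0.017
UNCW,18,Late,75.96,29.33,-46.63,0.970,0.945,-0.025
UNCW,23,Late,88.48,70.68,-17.80,0.980,0.961,-0.019
Mote,0,Early,60.13,41.37,-18.76,0.995,1.057,-0.052
Mote,8,Early/Late,67.93,89.31,21.38,1.036,1.003,0.033
Mote,15,Late,93.10,73.10,-20.00,0.999,0.966,-0.033
Mote,21,Late,95.29,84.94,-10.35,0.997,0.971,-0.026
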