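subject_id,timepoint,p_stay_cr,p_stay_rr,p_stay_cu,p_stay_ru,n_cr,n_rr,n_cu,n_ru,mb1,mb2
ddm_1,baseline,0.9333333333,0.75,0.7333333333,0.5,15,4,15,4,-0.05,-0.1291419275
ddm_1,followup,1,0.8333333333,0.8235294118,1,13,6,17,2,0.3431372549,0.197462587
ddm_2,baseline,1,1,0.5625,1,14,1,16,7,0.4375,0.0747465668
ddm_2,followup,1,1,1,1,12,7,12,7,0,-0.0552313667
ddm_3,baseline,0.8888888889,0.7142857143,0.5555555556,0.75,18,7,9,4,0.369047619,0.2671289137
ddm_3,followup,0.95,0.6666666667,0.6666666667,1,20,6,9,3,0.6166666667,0.1166522207
rl_1,baseline,0.8888888889,0.5,0.6470588235,0.5,9,2,17,10,0.2418300654,
rl_1,followup,0.625,0.7142857143,0.4736842105,0.5,8,7,19,4,-0.0629699248,
rl_2,baseline,0.5882352941,0.6666666667,0.7272727273,0.75,17,6,11,4,-0.0557040998,
rl_2,followup,0.8235294118,0.8,0.4166666667,0.5,17,5,12,4,0.1068627451,
rl_3,baseline,0.875,0.6,0.5384615385,0.75,16,5,13,4,0.4865384615,
rl_3,followup,0.9047619048,0.6666666667,0.6,0.75,21,3,10,4,0.3880952381,
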