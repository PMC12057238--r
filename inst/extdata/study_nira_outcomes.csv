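item,baseline,post_alleviating,nira_alleviating,post_aggravating,nira_aggravating
PHQ1,6.17,4.10,2.07,7.21,1.04
PHQ2,6.17,4.34,1.83,7.33,1.16
PHQ3,6.17,5.60,0.56,8.42,2.25
PHQ4,6.17,4.63,1.54,7.73,1.57
PHQ5,6.17,4.70,1.47,7.88,1.71
PHQ6,6.17,5.34,0.82,8.89,2.72
PHQ7,6.17,5.71,0.46,8.05,1.88
PHQ8,6.17,5.69,0.48,8.12,1.95
PHQ9,6.17,5.71,0.46,8.24,2.07
GAD1,6.17,4.90,1.27,7.43,1.26
GAD2,6.17,5.02,1.15,7.26,1.09
GAD3,6.17,5.11,1.06,7.86,1.69
GAD4,6.17,4.87,1.30,7.38,1.21
GAD5,6.17,5.10,1.07,7.38,1.21
GAD6,6.17,4.98,1.19,7.66,1.49
GAD7,6.17,5.05,1.12,8.04,1.87
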