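item,name,scale,mean,sd,skewness,kurtosis,ei_std,bridge_ei_std
PHQ1,Anhedonia,PHQ,0.76,0.59,0.27,0.37,0.72,-0.89
PHQ2,Depressed or sad mood,PHQ,0.80,0.68,0.73,1.10,-0.07,-0.89
PHQ3,Sleep difficulties,PHQ,0.36,0.69,2.08,3.94,0.01,0.24
PHQ4,Fatigue,PHQ,0.53,0.68,1.22,1.36,0.60,-0.35
PHQ5,Appetite changes,PHQ,0.51,0.68,1.42,2.38,1.35,-0.89
PHQ6,Guilt,PHQ,0.23,0.57,2.59,6.35,2.41,2.28
PHQ7,Concentration difficulties,PHQ,0.32,0.63,2.31,5.88,-0.32,-0.89
PHQ8,Motor disturbances,PHQ,0.31,0.57,1.77,2.79,0.61,-0.44
PHQ9,Suicide ideation,PHQ,0.22,0.53,2.76,8.49,-0.43,0.94
GAD1,Anxiousness,GAD,0.63,0.64,0.78,0.70,-0.85,0.22
GAD2,Uncontrollable worry,GAD,0.54,0.69,1.14,0.96,-1.47,-0.26
GAD3,Excessive worry,GAD,0.47,0.74,1.70,2.59,-0.58,1.72
GAD4,Trouble relaxing,GAD,0.60,0.71,1.12,1.21,-1.00,0.17
GAD5,Restlessness,GAD,0.58,0.64,0.83,0.53,-1.13,-0.89
GAD6,Irritability,GAD,0.53,0.68,1.23,1.52,-0.32,-0.89
GAD7,Feeling afraid,GAD,0.45,0.64,1.31,1.36,0.46,0.82
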