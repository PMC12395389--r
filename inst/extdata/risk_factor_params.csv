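name,prevalence,odds_ratio,beta,par_pct
hypertension,0.580,3.00,1.097,0.505
diabetes,0.297,2.21,0.793,0.174
dyslipidemia,0.297,0.94,-0.060,0.196
heart_disease,0.691,1.24,0.211,0.504
smoking,0.213,0.88,-0.133,0.082
overweight,0.054,1.51,0.411,0.021
physical_inactivity,0.515,1.01,0.010,0.349
family_history,0.085,1.40,0.338,0.051
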