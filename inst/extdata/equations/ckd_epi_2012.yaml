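# CKD-EPI 2012 creatinine-cystatin C equation (Scr mg/dL, Scys mg/L).
# eGFR = 135 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-0.601
#        * min(Scys/0.8, 1)^-0.375 * max(Scys/0.8, 1)^-0.711
#        * 0.995^age * 0.969[female] * 1.08[black]
equation: ckd_epi_2012
version: 1
output_unit: mL/min/1.73m2
creatinine_unit: mg/dL
intercept: 135
kappa: {female: 0.7, male: 0.9}
alpha: {female: -0.248, male: -0.207}
creatinine_max_exponent: -0.601
cystatin_knot: 0.8
cystatin_min_exponent: -0.375
cystatin_max_exponent: -0.711
age_base: 0.995
female_factor: 0.969
black_factor: 1.08
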