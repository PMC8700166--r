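# CKD-EPI 2012 cystatin C equation (serum cystatin C in mg/L).
# eGFR = 133 * min(Scys/0.8, 1)^-0.499 * max(Scys/0.8, 1)^-1.328
#        * 0.996^age * 0.932[female]
equation: ckd_epi_cys
version: 1
output_unit: mL/min/1.73m2
intercept: 133
cystatin_knot: 0.8
min_exponent: -0.499
max_exponent: -1.328
age_base: 0.996
female_factor: 0.932
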