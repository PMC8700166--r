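# European Kidney Function Consortium creatinine equation.
# eGFR = 107.3 * (Scr/Q)^-alpha * (0.990^(age - 40) when age > 40)
# alpha = 0.322 when Scr/Q < 1, else 1.132.
# Q is the sex-specific creatinine rescaling constant; for ages below 25
# Q follows the published age polynomial, ln(Q[umol/L]) =
#   a0 + a1*age + a2*ln(age) + a3*age^2 + a4*age^3.
equation: ekfc
version: 1
output_unit: mL/min/1.73m2
creatinine_unit: mg/dL
intercept: 107.3
alpha_low: 0.322
alpha_high: 1.132
age_knot: 40
age_base: 0.990
adult_q_mg_dl: {female: 0.70, male: 0.90}
adult_age: 25
young_q_log_umol_poly:
  female: [3.080, 0.177, -0.223, -0.00596, 0.0000686]
  male: [3.200, 0.259, -0.543, -0.00763, 0.0000790]
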