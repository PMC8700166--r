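# GFR-NMR piecewise power-law equation.
# eGFR = intercept * cystatin_c^pivot_exponent * creatinine^creatinine_exponent
#        * valine^valine_exponent * myo_inositol_base^myo_inositol
#        * age_base^age
# Branch chosen by sex and serum cystatin C against the sex-specific cutoff;
# a value exactly at the cutoff takes the at_or_above branch.
equation: gfr_nmr
version: 1
output_unit: mL/min/1.73m2
units:
  creatinine: umol/L
  cystatin_c: mg/L
  valine: umol/L
  myo_inositol: umol/L
  age: years
shared:
  creatinine_exponent: -0.3798
  valine_exponent: 0.1628
  myo_inositol_base: 0.9979
  age_base: 0.9963
pivot_marker: cystatin_c
branches:
  - sex: female
    side: below
    pivot_cutoff: 1.02
    intercept: 238
    pivot_exponent: -0.4114
  - sex: female
    side: at_or_above
    pivot_cutoff: 1.02
    intercept: 239
    pivot_exponent: -0.6443
  - sex: male
    side: below
    pivot_cutoff: 1.22
    intercept: 266
    pivot_exponent: -0.5867
  - sex: male
    side: at_or_above
    pivot_cutoff: 1.22
    intercept: 269
    pivot_exponent: -0.6419
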