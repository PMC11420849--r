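quantity,value
n_patients,9
n_male,6
n_female,3
age_median_yr,9
age_min_yr,5
age_max_yr,11
height_median_cm,130.4
height_min_cm,115
height_max_cm,148.5
weight_median_kg,21.9
weight_min_kg,18.5
weight_max_kg,32.45
bmi_median,14.1
bmi_min,12.5
bmi_max,18.2
bsa_median_m2,0.90
bsa_min_m2,0.80
bsa_max_m2,1.13
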