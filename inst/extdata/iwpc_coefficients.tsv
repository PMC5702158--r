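# IWPC pharmacogenetic dosing algorithm coefficients, square-root weekly-dose scale.
# Source: International Warfarin Pharmacogenetics Consortium, N Engl J Med 2009;360:753-764,
# supplementary appendix ("pharmacogenetic dose algorithm"). sqrt(mg/week) = intercept + sum(term effects).
# term	level	coefficient
term	level	coefficient
intercept	.	5.6044
age_decades	.	-0.2614
height_cm	.	0.0087
weight_kg	.	0.0128
vkorc1_class	AG	-0.8677
vkorc1_class	AA	-1.6974
vkorc1_class	unknown	-0.4854
cyp2c9_class	*1/*2	-0.5211
cyp2c9_class	*1/*3	-0.9357
cyp2c9_class	*2/*2	-1.0616
cyp2c9_class	*2/*3	-1.9206
cyp2c9_class	*3/*3	-2.3312
cyp2c9_class	unknown	-0.2188
race_class	asian	-0.1092
race_class	black_or_AA	-0.2760
race_class	missing_or_mixed	-0.1032
enzyme_inducer	1	1.1816
amiodarone	1	-0.5503
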