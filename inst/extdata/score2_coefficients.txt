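# SCORE2 model constants: log-subdistribution-hazard coefficients on centered
# covariates, 10-year baseline survival, and region/sex recalibration scales
# (ESC 2021 SCORE2 working group publication, supplementary material).
# Covariate centering: cage=(age-60)/5, csbp=(sbp-120)/20, ctotalc=(totalc-6)/1,
# chdlc=(hdlc-1.3)/0.5; interaction terms multiply the centered covariate by cage.
# kind: coef (term coefficient), baseline (10-year baseline survival),
#       scale1/scale2 (recalibration: risk = 1-exp(-exp(scale1+scale2*cloglog))).
kind sex region term value
coef female - age_per5 0.4648
coef female - smoking 0.7744
coef female - sbp_per20 0.3131
coef female - totalc_per1 0.1002
coef female - hdlc_per05 -0.2606
coef female - diabetes 0.8096
coef female - smoking_x_age -0.1088
coef female - sbp_x_age -0.0277
coef female - totalc_x_age -0.0226
coef female - hdlc_x_age 0.0613
coef female - diabetes_x_age -0.1272
baseline female - s0_10 0.9776
coef male - age_per5 0.3742
coef male - smoking 0.6012
coef male - sbp_per20 0.2777
coef male - totalc_per1 0.1458
coef male - hdlc_per05 -0.2698
coef male - diabetes 0.6457
coef male - smoking_x_age -0.0755
coef male - sbp_x_age -0.0255
coef male - totalc_x_age -0.0281
coef male - hdlc_x_age 0.0426
coef male - diabetes_x_age -0.0983
baseline male - s0_10 0.9605
scale1 female low - -0.7380
scale2 female low - 0.7019
scale1 male low - -0.5699
scale2 male low - 0.7476
scale1 female moderate - -0.3143
scale2 female moderate - 0.7701
scale1 male moderate - -0.1565
scale2 male moderate - 0.8009
scale1 female high - 0.5710
scale2 female high - 0.9369
scale1 male high - 0.3207
scale2 male high - 0.9360
scale1 female very_high - 0.9412
scale2 female very_high - 0.8329
scale1 male very_high - 0.5836
scale2 male very_high - 0.8294
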