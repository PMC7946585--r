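n_participants: 72.0
study_days: 91.0
messages_per_week: 2.0
engagement_model:
  smbg:
    shape1: 0.614
    shape2: 0.473
  diet:
    shape1: 0.294
    shape2: 0.792
  exercise:
    shape1: 0.545
    shape2: 0.363
  read:
    shape1: 1.024
    shape2: 0.316
covariate_model:
  age:
  - 51.399999999999999
  - 7.9
  sex_female: 0.417
  bmi:
  - 26.0
  - 3.3
  sbp:
  - 137.099999999999994
  - 16.0
  dbp:
  - 87.0
  - 10.4
  hba1c_baseline:
  - 8.130000000000001
  - 1.46
  total_chol:
  - 170.099999999999994
  - 32.5
  tg:
  - 146.900000000000006
  - 61.299999999999997
  hdl:
  - 47.399999999999999
  - 11.300000000000001
  ldl:
  - 93.200000000000003
  - 30.0
  smoker: 0.264
  drinker: 0.417
  dm_duration:
  - 7.26
  - 5.15
  insulin: 0.222
  antihypertensive: 0.375
  antidyslipidemic: 0.528
  sdsca_diet:
  - 11.0
  - 6.0
  sdsca_exercise:
  - 6.0
  - 4.0
  sdsca_glucose:
  - 3.9
  - 4.8
  sdsca_foot:
  - 3.4
  - 3.7
  ads_total:
  - 19.5
  - 4.4
true_effects:
  beta_uus_by_visit:
    '3': -0.113
    '6': -0.143
    '12': -0.136
  gamma_baseline_hba1c: -0.3
  residual_sd_by_visit:
    '3': 1.0
    '6': 1.05
    '12': 1.05
  secondary_effects:
    bmi: 0.0
    sbp: 0.0
    dbp: 0.0
    total_chol: 0.0
    tg: 0.0
    hdl: 0.0
    ldl: 0.0
    sdsca_diet: 0.0
    sdsca_exercise: 0.0
    sdsca_glucose: 0.0
    sdsca_foot: 0.0
    ads_total: 0.0
  secondary_change_sd:
    bmi: 0.9
    sbp: 15.800000000000001
    dbp: 9.300000000000001
    total_chol: 32.0
    tg: 66.0
    hdl: 7.3
    ldl: 30.0
    sdsca_diet: 6.7
    sdsca_exercise: 3.4
    sdsca_glucose: 5.6
    sdsca_foot: 5.2
    ads_total: 4.5
dropout_model:
  low: 0.394736842105263
  high: 0.088235294117647
seed: 1
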