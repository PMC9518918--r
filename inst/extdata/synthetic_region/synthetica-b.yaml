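schema_version: 1
name: Synthetica-B
population: 44505939
incidence:
  point: 88.919084439985454
  low: 65.615207270568376
  high: 112.22296160940255
  family: gamma
profile:
- sex: female
  age_low: 0
  age_high: 15
  share: 0.085820850104076862
  mean_age_at_death: 11.800000000000001
- sex: male
  age_low: 0
  age_high: 15
  share: 0.18988857597300585
  mean_age_at_death: 11.800000000000001
- sex: female
  age_low: 15
  age_high: 99
  share: 0.22545196825826347
  mean_age_at_death: 34.5
- sex: male
  age_low: 15
  age_high: 99
  share: 0.49883860566465382
  mean_age_at_death: 34.5
probabilities:
  p_conventional_first:
    point: 0.43978428245754914
    low: 0.3245257981402917
    high: 0.55504276677480657
    family: beta
  p_switch_to_conventional:
    point: 0.42825074717402456
    low: 0.31601496705203808
    high: 0.5404865272960111
    family: beta
  p_indicated:
    point: 0.40319362375885248
    low: 0.29752480426138983
    high: 0.50886244325631513
    family: beta
  p_adr:
    point: 0.32515901555307208
    low: 0.23994147415911338
    high: 0.41037655694703085
    family: beta
  p_death_treated:
    point: 0.018795982885174457
    low: 0.013869939402009654
    high: 0.023722026368339262
    family: beta
  rr_death_untreated:
    point: 2.3300000000000001
    low: 1.26
    high: 4.0599999999999996
    family: lognormal
  p_amputation_survivor:
    point: 0.027234047256642954
    low: 0.020096559324867626
    high: 0.03437153518841829
    family: beta
antivenom_courses: 6405.8621874188211
lengths_of_stay:
  los_indicated:
    point: 3.2226896295323968
    low: 2.3780884535895028
    high: 4.0672908054752916
    family: gamma
  los_not_indicated:
    point: 2.9700670870952308
    low: 2.1916731234314395
    high: 3.7484610507590226
    family: gamma
unit_costs:
  hospital_day:
    point: 30556.075294452534
    low: 22547.951617448351
    high: 38564.198971456717
    family: gamma
  antivenom_course:
    point: 298343.43136177026
    low: 220153.7072711041
    high: 376533.15545243648
    family: gamma
  antivenom_logistics:
    point: 42015.104336640179
    low: 31003.803029527149
    high: 53026.405643753213
    family: gamma
  adr_management:
    point: 49429.824855189821
    low: 36475.27663659447
    high: 62384.37307378518
    family: gamma
  amputation:
    point: 1585316.7340880586
    low: 1169837.5748222617
    high: 2000795.8933538557
    family: gamma
  transport:
    point: 16544.221639208576
    low: 12208.318819561957
    high: 20880.124458855196
    family: gamma
  food_person_day:
    point: 4554.4846282425497
    low: 3360.8471654299606
    high: 5748.1220910551392
    family: gamma
economics:
  exchange_rate: 817.11000000000001
  gdp_per_capita: 3661
  gdp_growth:
    point: 0.056074769613333048
    low: 0.046074769613333046
    high: 0.066074769613333043
    family: uniform
  discount_rate:
    point: 0.029999999999999999
    low: 0
    high: 0.059999999999999998
    family: uniform
  retirement_age: 60
  daily_income_divisor: 365
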