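schema_version: 1
name: Synthetica-E
population: 31133386
incidence:
  point: 66.979580863844603
  low: 51.570889885156951
  high: 82.388271842532262
  family: gamma
profile:
- sex: female
  age_low: 0
  age_high: 15
  share: 0.050980761462597217
  mean_age_at_death: 8.8000000000000007
- sex: male
  age_low: 0
  age_high: 15
  share: 0.085772229915710124
  mean_age_at_death: 8.8000000000000007
- sex: female
  age_low: 15
  age_high: 99
  share: 0.32181372697068555
  mean_age_at_death: 35
- sex: male
  age_low: 15
  age_high: 99
  share: 0.54143328165100713
  mean_age_at_death: 35
probabilities:
  p_conventional_first:
    point: 0.65012715341290461
    low: 0.50056502903716393
    high: 0.7996892777886454
    family: beta
  p_switch_to_conventional:
    point: 0.22086270293220878
    low: 0.17005311149690111
    high: 0.2716722943675165
    family: beta
  p_indicated:
    point: 0.1040212132036686
    low: 0.0800910734683703
    high: 0.12795135293896692
    family: beta
  p_adr:
    point: 0.12220436616335065
    low: 0.094091181664850643
    high: 0.15031755066185068
    family: beta
  p_death_treated:
    point: 0.019521750557236373
    low: 0.015030760649267984
    high: 0.024012740465204765
    family: beta
  rr_death_untreated:
    point: 2.3300000000000001
    low: 1.26
    high: 4.0599999999999996
    family: lognormal
  p_amputation_survivor:
    point: 0.046725074415327986
    low: 0.035975944257503834
    high: 0.057474204573152145
    family: beta
antivenom_courses: 1506.8937531077186
lengths_of_stay:
  los_indicated:
    point: 3.8290316024795175
    low: 2.9481606870557346
    high: 4.7099025179033003
    family: gamma
  los_not_indicated:
    point: 2.0760282594710588
    low: 1.5984367681441871
    high: 2.5536197507979308
    family: gamma
unit_costs:
  hospital_day:
    point: 536.97829895466566
    low: 413.4461334179274
    high: 660.51046449140404
    family: gamma
  antivenom_course:
    point: 3272.4543492497878
    low: 2519.6243500302608
    high: 4025.2843484693153
    family: gamma
  antivenom_logistics:
    point: 852.64344175801307
    low: 656.49232914115566
    high: 1048.7945543748706
    family: gamma
  adr_management:
    point: 976.53168571235153
    low: 751.88001154577091
    high: 1201.1833598789324
    family: gamma
  amputation:
    point: 10362.302270156797
    low: 7978.4486919569845
    high: 12746.155848356611
    family: gamma
  transport:
    point: 289.03677825721684
    low: 222.54370170759924
    high: 355.52985480683446
    family: gamma
  food_person_day:
    point: 10.858262632994448
    low: 8.3603130889781578
    high: 13.356212177010738
    family: gamma
economics:
  exchange_rate: 9.1300000000000008
  gdp_per_capita: 6409
  gdp_growth:
    point: 0.06575456421589479
    low: 0.055754564215894788
    high: 0.075754564215894785
    family: uniform
  discount_rate:
    point: 0.029999999999999999
    low: 0
    high: 0.059999999999999998
    family: uniform
  retirement_age: 60
  daily_income_divisor: 365
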