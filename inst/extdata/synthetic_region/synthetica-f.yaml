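schema_version: 1
name: Synthetica-F
population: 28129685
incidence:
  point: 125.54936084197834
  low: 110.94542025276942
  high: 140.15330143118726
  family: gamma
profile:
- sex: female
  age_low: 0
  age_high: 15
  share: 0.065216051502350381
  mean_age_at_death: 12.6
- sex: male
  age_low: 0
  age_high: 15
  share: 0.1342484292628135
  mean_age_at_death: 12.6
- sex: female
  age_low: 15
  age_high: 99
  share: 0.26173966137532928
  mean_age_at_death: 44.299999999999997
- sex: male
  age_low: 15
  age_high: 99
  share: 0.53879585785950679
  mean_age_at_death: 44.299999999999997
probabilities:
  p_conventional_first:
    point: 0.50319892009720213
    low: 0.44466666565663204
    high: 0.56173117453777222
    family: beta
  p_switch_to_conventional:
    point: 0.5713029572740197
    low: 0.50484882010823728
    high: 0.63775709443980222
    family: beta
  p_indicated:
    point: 0.59879116006195543
    low: 0.52913958662308513
    high: 0.66844273350082584
    family: beta
  p_adr:
    point: 0.13089600587263703
    low: 0.11567014187533044
    high: 0.14612186986994363
    family: beta
  p_death_treated:
    point: 0.016835245350375772
    low: 0.014876964390179614
    high: 0.018793526310571934
    family: beta
  rr_death_untreated:
    point: 2.3300000000000001
    low: 1.26
    high: 4.0599999999999996
    family: lognormal
  p_amputation_survivor:
    point: 0.0028152337330393492
    low: 0.0024877648721361809
    high: 0.0031427025939425178
    family: beta
antivenom_courses: 2281.8015138921123
lengths_of_stay:
  los_indicated:
    point: 3.9876783564686775
    low: 3.5238303733631255
    high: 4.4515263395742295
    family: gamma
  los_not_indicated:
    point: 1.2076737727038562
    low: 1.0671967849323987
    high: 1.348150760475314
    family: gamma
unit_costs:
  hospital_day:
    point: 130.81603721830061
    low: 115.59947519966676
    high: 146.03259923693449
    family: gamma
  antivenom_course:
    point: 4014.2066707000135
    low: 3547.2729058559635
    high: 4481.1404355440636
    family: gamma
  antivenom_logistics:
    point: 993.66812117843756
    low: 878.08433716104628
    high: 1109.2519051958288
    family: gamma
  adr_management:
    point: 365.04151196256277
    low: 322.57977008236207
    high: 407.50325384276351
    family: gamma
  amputation:
    point: 15199.890100218123
    low: 13431.834169885818
    high: 16967.946030550429
    family: gamma
  transport:
    point: 69.788822527683806
    low: 61.670965047963648
    high: 77.906680007403963
    family: gamma
  food_person_day:
    point: 71.666284438914147
    low: 63.330040007430689
    high: 80.002528870397612
    family: gamma
economics:
  exchange_rate: 11.27
  gdp_per_capita: 2552
  gdp_growth:
    point: 0.050722960818093271
    low: 0.040722960818093269
    high: 0.060722960818093273
    family: uniform
  discount_rate:
    point: 0.029999999999999999
    low: 0
    high: 0.059999999999999998
    family: uniform
  retirement_age: 60
  daily_income_divisor: 365
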