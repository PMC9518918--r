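schema_version: 1
name: Synthetica-C
population: 8312561
incidence:
  point: 129.32178563205525
  low: 114.84885440105636
  high: 143.79471686305416
  family: gamma
profile:
- sex: female
  age_low: 0
  age_high: 15
  share: 0.081682466806860907
  mean_age_at_death: 13.6
- sex: male
  age_low: 0
  age_high: 15
  share: 0.099881875656528132
  mean_age_at_death: 13.6
- sex: female
  age_low: 15
  age_high: 99
  share: 0.36819918781004995
  mean_age_at_death: 32.5
- sex: male
  age_low: 15
  age_high: 99
  share: 0.45023646972656101
  mean_age_at_death: 32.5
probabilities:
  p_conventional_first:
    point: 0.39457305039977658
    low: 0.35041476263618787
    high: 0.43873133816336535
    family: beta
  p_switch_to_conventional:
    point: 0.53282945621758704
    low: 0.4731983272473404
    high: 0.59246058518783373
    family: beta
  p_indicated:
    point: 0.8329862087965012
    low: 0.73976330704518201
    high: 0.92620911054782051
    family: beta
  p_adr:
    point: 0.28546475826296952
    low: 0.25351722680088001
    high: 0.31741228972505908
    family: beta
  p_death_treated:
    point: 0.020679976742248984
    low: 0.018365595760062497
    high: 0.02299435772443547
    family: beta
  rr_death_untreated:
    point: 2.3300000000000001
    low: 1.26
    high: 4.0599999999999996
    family: lognormal
  p_amputation_survivor:
    point: 0.0012777333618141712
    low: 0.0011347369827686151
    high: 0.0014207297408597274
    family: beta
antivenom_courses: 1478.8990517952159
lengths_of_stay:
  los_indicated:
    point: 4.5153995016589761
    low: 4.0100626309330094
    high: 5.0207363723849427
    family: gamma
  los_not_indicated:
    point: 2.6205021594651043
    low: 2.3272310191134693
    high: 2.9137732998167398
    family: gamma
unit_costs:
  hospital_day:
    point: 244.55004764787853
    low: 217.18144919521424
    high: 271.91864610054284
    family: gamma
  antivenom_course:
    point: 1721.0858604166656
    low: 1528.4720855703595
    high: 1913.6996352629719
    family: gamma
  antivenom_logistics:
    point: 460.34246279315244
    low: 408.8236504433907
    high: 511.86127514291417
    family: gamma
  adr_management:
    point: 654.76856949049977
    low: 581.49073442087183
    high: 728.04640456012783
    family: gamma
  amputation:
    point: 16725.935291792266
    low: 14854.067299333587
    high: 18597.803284250946
    family: gamma
  transport:
    point: 306.15263004684823
    low: 271.8898340360949
    high: 340.41542605760162
    family: gamma
  food_person_day:
    point: 41.584903693133967
    low: 36.930966628648704
    high: 46.238840757619236
    family: gamma
economics:
  exchange_rate: 8.8399999999999999
  gdp_per_capita: 1104
  gdp_growth:
    point: 0.027718587375711652
    low: 0.01771858737571165
    high: 0.037718587375711654
    family: uniform
  discount_rate:
    point: 0.029999999999999999
    low: 0
    high: 0.059999999999999998
    family: uniform
  retirement_age: 60
  daily_income_divisor: 365
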