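schema_version: 1
name: Synthetica-D
population: 66166068
incidence:
  point: 26.48874347913079
  low: 19.375039154115989
  high: 33.602447804145598
  family: gamma
profile:
- sex: female
  age_low: 0
  age_high: 15
  share: 0.049273028825922237
  mean_age_at_death: 9
- sex: male
  age_low: 0
  age_high: 15
  share: 0.066822625048877371
  mean_age_at_death: 9
- sex: female
  age_low: 15
  age_high: 99
  share: 0.37514448536508682
  mean_age_at_death: 43.100000000000001
- sex: male
  age_low: 15
  age_high: 99
  share: 0.50875986076011359
  mean_age_at_death: 43.100000000000001
probabilities:
  p_conventional_first:
    point: 0.92800395026570182
    low: 0.67878315503103981
    high: 1
    family: beta
  p_switch_to_conventional:
    point: 0.34825530713424085
    low: 0.25472934254773566
    high: 0.4417812717207461
    family: beta
  p_indicated:
    point: 0.69995135664939878
    low: 0.51197539633177491
    high: 0.88792731696702265
    family: beta
  p_adr:
    point: 0.22131990855559708
    low: 0.16188317491271104
    high: 0.28075664219848318
    family: beta
  p_death_treated:
    point: 0.0013456294888164848
    low: 0.00098425295459156283
    high: 0.0017070060230414067
    family: beta
  rr_death_untreated:
    point: 2.3300000000000001
    low: 1.26
    high: 4.0599999999999996
    family: lognormal
  p_amputation_survivor:
    point: 0.0036498901734594259
    low: 0.0026696911869267758
    high: 0.0046300891599920764
    family: beta
antivenom_courses: 11515.813242098931
lengths_of_stay:
  los_indicated:
    point: 5.0096395956352353
    low: 3.6642720856092299
    high: 6.3550071056612412
    family: gamma
  los_not_indicated:
    point: 2.6560995331965387
    low: 1.9427887356550757
    high: 3.3694103307380021
    family: gamma
unit_costs:
  hospital_day:
    point: 2078.3605691511184
    low: 1520.2048913871351
    high: 2636.5162469151019
    family: gamma
  antivenom_course:
    point: 5787.6464973203838
    low: 4233.340761675282
    high: 7341.9522329654865
    family: gamma
  antivenom_logistics:
    point: 1344.4562940347562
    low: 983.39482801227439
    high: 1705.5177600572381
    family: gamma
  adr_management:
    point: 2201.4842515390364
    low: 1610.2630011251185
    high: 2792.7055019529544
    family: gamma
  amputation:
    point: 31288.692323157564
    low: 22885.934144814288
    high: 39691.450501500847
    family: gamma
  transport:
    point: 190.23432175442576
    low: 139.14580113445399
    high: 241.32284237439754
    family: gamma
  food_person_day:
    point: 38.326306293793024
    low: 28.033556429730993
    high: 48.619056157855063
    family: gamma
economics:
  exchange_rate: 15.76
  gdp_per_capita: 10880
  gdp_growth:
    point: 0.057584497849456975
    low: 0.047584497849456973
    high: 0.06758449784945697
    family: uniform
  discount_rate:
    point: 0.029999999999999999
    low: 0
    high: 0.059999999999999998
    family: uniform
  retirement_age: 60
  daily_income_divisor: 365
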