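schema_version: 1
name: Synthetica-G
population: 8709660
incidence:
  point: 8.830720525002107
  low: 5.9202453653473786
  high: 11.741195684656837
  family: gamma
profile:
- sex: female
  age_low: 0
  age_high: 15
  share: 0.10885985852538446
  mean_age_at_death: 11.800000000000001
- sex: male
  age_low: 0
  age_high: 15
  share: 0.13615927360632618
  mean_age_at_death: 11.800000000000001
- sex: female
  age_low: 15
  age_high: 99
  share: 0.33543139978691161
  mean_age_at_death: 40.100000000000001
- sex: male
  age_low: 15
  age_high: 99
  share: 0.41954946808137772
  mean_age_at_death: 40.100000000000001
probabilities:
  p_conventional_first:
    point: 0.79679869102546941
    low: 0.5341856017640495
    high: 1
    family: beta
  p_switch_to_conventional:
    point: 0.31904479991644619
    low: 0.21389234238539914
    high: 0.42419725744749326
    family: beta
  p_indicated:
    point: 0.74182427600026135
    low: 0.4973299426086949
    high: 0.98631860939182792
    family: beta
  p_adr:
    point: 0.10077048963867127
    low: 0.067558023443051646
    high: 0.13398295583429093
    family: beta
  p_death_treated:
    point: 0.00056803555181249982
    low: 0.00038081941710749477
    high: 0.00075525168651750492
    family: beta
  rr_death_untreated:
    point: 2.3300000000000001
    low: 1.26
    high: 4.0599999999999996
    family: lognormal
  p_amputation_survivor:
    point: 0.023596796747064219
    low: 0.015819640785066938
    high: 0.031373952709061508
    family: beta
antivenom_courses: 550.27344300228037
lengths_of_stay:
  los_indicated:
    point: 3.2208609385415912
    low: 2.1593127072521314
    high: 4.2824091698310509
    family: gamma
  los_not_indicated:
    point: 2.5391671503894031
    low: 1.7022951311135042
    high: 3.3760391696653023
    family: gamma
unit_costs:
  hospital_day:
    point: 259482.5875011459
    low: 173960.95615217515
    high: 345004.21885011665
    family: gamma
  antivenom_course:
    point: 621885.24502369389
    low: 416921.04615988448
    high: 826849.44388750335
    family: gamma
  antivenom_logistics:
    point: 164786.73833375273
    low: 110475.46133172163
    high: 219098.01533578386
    family: gamma
  adr_management:
    point: 102489.79359429702
    low: 68710.670188704855
    high: 136268.91699988919
    family: gamma
  amputation:
    point: 2080739.6155190095
    low: 1394958.5461791256
    high: 2766520.684858894
    family: gamma
  transport:
    point: 73302.06124116201
    low: 49142.7836612795
    high: 97461.338821044526
    family: gamma
  food_person_day:
    point: 5717.8289521159604
    low: 3833.3169142622705
    high: 7602.3409899696508
    family: gamma
economics:
  exchange_rate: 1976.8
  gdp_per_capita: 8125
  gdp_growth:
    point: 0.049345866199582818
    low: 0.039345866199582816
    high: 0.05934586619958282
    family: uniform
  discount_rate:
    point: 0.029999999999999999
    low: 0
    high: 0.059999999999999998
    family: uniform
  retirement_age: 60
  daily_income_divisor: 365
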