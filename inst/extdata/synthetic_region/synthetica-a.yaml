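schema_version: 1
name: Synthetica-A
population: 14212093
incidence:
  point: 17.522572063608095
  low: 13.909152598553009
  high: 21.135991528663183
  family: gamma
profile:
- sex: female
  age_low: 0
  age_high: 15
  share: 0.067093082418194311
  mean_age_at_death: 9.8000000000000007
- sex: male
  age_low: 0
  age_high: 15
  share: 0.13399136318499752
  mean_age_at_death: 9.8000000000000007
- sex: female
  age_low: 15
  age_high: 99
  share: 0.26656316939648778
  mean_age_at_death: 33.700000000000003
- sex: male
  age_low: 15
  age_high: 99
  share: 0.53235238500032045
  mean_age_at_death: 33.700000000000003
probabilities:
  p_conventional_first:
    point: 0.74977920610690485
    low: 0.59516339011793806
    high: 0.90439502209587175
    family: beta
  p_switch_to_conventional:
    point: 0.30849153334274887
    low: 0.24487591188381519
    high: 0.3721071548016826
    family: beta
  p_indicated:
    point: 0.19670536238700154
    low: 0.15614174063388611
    high: 0.23726898414011699
    family: beta
  p_adr:
    point: 0.15869735502637922
    low: 0.12597155942836707
    high: 0.19142315062439139
    family: beta
  p_death_treated:
    point: 0.00088170927937608222
    low: 0.00069988748625964415
    high: 0.0010635310724925204
    family: beta
  rr_death_untreated:
    point: 2.3300000000000001
    low: 1.26
    high: 4.0599999999999996
    family: lognormal
  p_amputation_survivor:
    point: 0.049307555340230465
    low: 0.039139591436649142
    high: 0.059475519243811795
    family: beta
antivenom_courses: 477.3245460131003
lengths_of_stay:
  los_indicated:
    point: 5.4416216928511858
    low: 4.3194769714577168
    high: 6.5637664142446557
    family: gamma
  los_not_indicated:
    point: 1.850737324450165
    low: 1.469087287652133
    high: 2.2323873612481973
    family: gamma
unit_costs:
  hospital_day:
    point: 1701.4184204097837
    low: 1350.5602007263624
    high: 2052.2766400932051
    family: gamma
  antivenom_course:
    point: 10529.925494352356
    low: 8358.4955462401667
    high: 12701.355442464544
    family: gamma
  antivenom_logistics:
    point: 1058.695416631791
    low: 840.37640432383409
    high: 1277.0144289397481
    family: gamma
  adr_management:
    point: 1500.0800986330491
    low: 1190.7408870226795
    high: 1809.4193102434187
    family: gamma
  amputation:
    point: 27711.441608546767
    low: 21996.923092111469
    high: 33425.96012498207
    family: gamma
  transport:
    point: 781.89185940076129
    low: 620.6539284582725
    high: 943.12979034325019
    family: gamma
  food_person_day:
    point: 60.09845101099927
    low: 47.70524116061339
    high: 72.491660861385157
    family: gamma
economics:
  exchange_rate: 23.460000000000001
  gdp_per_capita: 11831
  gdp_growth:
    point: 0.025486076883971691
    low: 0.015486076883971691
    high: 0.035486076883971693
    family: uniform
  discount_rate:
    point: 0.029999999999999999
    low: 0
    high: 0.059999999999999998
    family: uniform
  retirement_age: 60
  daily_income_divisor: 365
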