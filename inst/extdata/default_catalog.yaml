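# Default beverage catalog -- PLACEHOLDER nutrition values.
#
# Container ounces use conventional package sizes; kcal/oz values are typical
# of widely marketed products in each category circa the early 2010s. They are
# NOT transcribed from any authoritative nutrition database: analyses of real
# survey data should supply a catalog built from such a source instead.
#
# frequency_map: times/day assigned to each survey frequency category.
# Midpoint rule for the bounded category (2-4 -> 3); lower bound for the
# open-ended top category (5+ -> 5); sub-daily consumption counts 0.5/day.
frequency_map:
  "Never": 0
  "I drink it but not every day": 0.5
  "1 time per day": 1
  "2-4 times per day": 3
  "5 or more times per day": 5
container_ounces:
  regular_soda:
    glass: 8
    can: 12
    bottle: 20
  fruit_drink:
    glass: 8
    pouch: 6
    juice_box: 6.75
    bottle: 20
  sports_drink:
    glass: 8
    bottle: 20
  energy_drink:
    can: 12
  flavored_water_tea:
    glass: 8
    bottle: 20
kcal_per_ounce:
  regular_soda:
    glass: 12.5
    can: 12.5
    bottle: 12.5
  fruit_drink:
    glass: 14
    pouch: 14
    juice_box: 14
    bottle: 14
  sports_drink:
    glass: 6.5
    bottle: 6.5
  energy_drink:
    can: 13
  flavored_water_tea:
    glass: 8
    bottle: 8
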