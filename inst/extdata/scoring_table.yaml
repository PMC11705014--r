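# Default mHFII scoring table: 11 food-group components, total score 0-18.
#
# direction: favourable  -> points = number of thresholds at or below the weekly
#                           group frequency ("at least" bands, closed at the cut-off)
#            limiting    -> points = number of thresholds at or above the weekly
#                           group frequency ("at most" bands, closed at the cut-off)
# thresholds: strictly increasing weekly frequencies (times/week); one threshold
#             per point, so length(thresholds) == max_points.
# A group's weekly frequency is the SUM of its member items' weekly frequencies.
index_name: mHFII
max_total: 18
components:
  - name: vegetables
    direction: favourable
    max_points: 2
    thresholds: [7, 14]
    items: [veg_fresh, veg_cooked, veg_root, legumes]
  - name: fruits_berries
    direction: favourable
    max_points: 2
    thresholds: [7, 14]
    items: [fruits_fresh, berries, citrus_fruits]
  - name: fibre_grains
    direction: favourable
    max_points: 2
    thresholds: [7, 14]
    items: [rye_bread, wholegrain_bread, porridge, wholegrain_cereal]
  - name: fish
    direction: favourable
    max_points: 2
    thresholds: [1, 2]
    items: [fish_dishes, fish_cold_cuts]
  - name: milk
    direction: favourable
    max_points: 2
    thresholds: [4, 7]
    items: [milk_glass, sour_milk]
  - name: vegetable_oil
    direction: favourable
    max_points: 1
    thresholds: [4]
    items: [oil_cooking, oil_dressing]
  - name: nuts_seeds
    direction: favourable
    max_points: 1
    thresholds: [4]
    items: [nuts_seeds]
  - name: fat_spreads
    direction: favourable
    max_points: 1
    thresholds: [6]
    items: [veg_fat_spread]
  - name: red_processed_meat
    direction: limiting
    max_points: 2
    thresholds: [1.5, 4]
    items: [red_meat_dishes, processed_meat, sausages]
  - name: ssb
    direction: limiting
    max_points: 2
    thresholds: [0.47, 1.5]
    items: [sugary_soft_drinks, energy_drinks]
  - name: snacks
    direction: limiting
    max_points: 1
    thresholds: [1.5]
    items: [sweets_chocolate, salty_snacks, sweet_pastry]
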