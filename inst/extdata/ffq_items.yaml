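# Default 52-item FFQ schema (item identifiers, one column per item in CSV input).
# Items not belonging to any mHFII component are parsed and carried through but
# never scored (coffee, tea, alcoholic beverages, ...).
items:
  # vegetables
  - veg_fresh
  - veg_cooked
  - veg_root
  - legumes
  # fruits and berries
  - fruits_fresh
  - berries
  - citrus_fruits
  # fibre-rich grains
  - rye_bread
  - wholegrain_bread
  - porridge
  - wholegrain_cereal
  # fish
  - fish_dishes
  - fish_cold_cuts
  # vegetable oil
  - oil_cooking
  - oil_dressing
  # nuts and seeds
  - nuts_seeds
  # milk
  - milk_glass
  - sour_milk
  # fat spreads
  - veg_fat_spread
  # red and processed meat
  - red_meat_dishes
  - processed_meat
  - sausages
  # sugar-sweetened beverages
  - sugary_soft_drinks
  - energy_drinks
  # snacks
  - sweets_chocolate
  - salty_snacks
  - sweet_pastry
  # unscored items
  - white_bread
  - rice_pasta
  - potato
  - breakfast_cereals
  - cheese
  - yogurt
  - ice_cream
  - eggs
  - poultry
  - meat_substitutes
  - pizza
  - hamburger
  - french_fries
  - ready_meals
  - fruit_juice
  - diet_soft_drinks
  - bottled_water
  - coffee
  - tea
  - wine
  - beer
  - cider
  - alcohol_free_beer
  - spirits
  - butter
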