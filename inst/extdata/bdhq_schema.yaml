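scales:
  scale1:
    labels:
    - never
    - less than once per week
    - once per week
    - 2-3 times per week
    - 4-6 times per week
    - once per day
    - 2 or more times per day
    weights:
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    - 7
  scale2:
    labels:
    - never
    - less than 1 cup per week
    - 1 cup per week
    - 2-3 cups per week
    - 4-6 cups per week
    - 1 cup per day
    - 2-3 cups per day
    - 4 or more cups per day
    weights:
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    - 7
    - 8
  scale3:
    labels:
    - never
    - less than once per week
    - once per week
    - twice per week
    - 3 times per week
    - 4 times per week
    - 5 times per week
    - 6 times per week
    - daily
    weights:
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    - 7
    - 8
    - 9
  scale4:
    labels:
    - never
    - less than 0.5 cup per week
    - 0.5 cup per week
    - 1 cup per week
    - 2 cups per day
    - 3 cups per day
    - 4 or more cups per day
    weights:
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    - 7
  scale5:
    labels:
    - very low
    - low
    - medium
    - high
    - very high
    weights:
    - 1
    - 2
    - 3
    - 4
    - 5
  scale6:
    labels:
    - 'no'
    - 'yes'
    weights:
    - 1
    - 2
variables:
- id: reduced_fat_milk_yogurt
  category: food_item
  scale: scale1
- id: milk_yogurt
  category: food_item
  scale: scale1
- id: chicken
  category: food_item
  scale: scale1
- id: pork_beef
  category: food_item
  scale: scale1
- id: ham_sausage_bacon
  category: food_item
  scale: scale1
- id: liver
  category: food_item
  scale: scale1
- id: squid_octopus_shrimp_shellfish
  category: food_item
  scale: scale1
- id: small_fish_with_bones
  category: food_item
  scale: scale1
- id: canned_tuna
  category: food_item
  scale: scale1
- id: dried_salted_fish
  category: food_item
  scale: scale1
- id: oily_fish
  category: food_item
  scale: scale1
- id: lean_fish
  category: food_item
  scale: scale1
- id: egg
  category: food_item
  scale: scale1
- id: tofu
  category: food_item
  scale: scale1
- id: natto
  category: food_item
  scale: scale1
- id: potatoes
  category: food_item
  scale: scale1
- id: pickled_green_leafy_vegetables
  category: food_item
  scale: scale1
- id: other_pickled_vegetables
  category: food_item
  scale: scale1
- id: lettuce_cabbage_raw
  category: food_item
  scale: scale1
- id: green_leafy_vegetables
  category: food_item
  scale: scale1
- id: cabbage_chinese_cabbage
  category: food_item
  scale: scale1
- id: carrots_pumpkin
  category: food_item
  scale: scale1
- id: japanese_radish_turnip
  category: food_item
  scale: scale1
- id: other_root_vegetables
  category: food_item
  scale: scale1
- id: tomatoes
  category: food_item
  scale: scale1
- id: mushrooms
  category: food_item
  scale: scale1
- id: seaweeds
  category: food_item
  scale: scale1
- id: western_confectioneries
  category: food_item
  scale: scale1
- id: japanese_confectioneries
  category: food_item
  scale: scale1
- id: rice_crackers
  category: food_item
  scale: scale1
- id: ice_cream
  category: food_item
  scale: scale1
- id: citrus_fruit
  category: food_item
  scale: scale1
- id: persimmon_strawberry_kiwifruit
  category: food_item
  scale: scale1
- id: other_fruits
  category: food_item
  scale: scale1
- id: mayonnaise
  category: food_item
  scale: scale1
- id: bread
  category: food_item
  scale: scale1
- id: buckwheat_noodles
  category: food_item
  scale: scale1
- id: japanese_wheat_noodles
  category: food_item
  scale: scale1
- id: chinese_noodles
  category: food_item
  scale: scale1
- id: pasta
  category: food_item
  scale: scale1
- id: other_grains
  category: food_item
  scale: scale1
- id: sugar
  category: food_item
  scale: scale1
- id: citrus_fruit_seasonal
  category: food_item
  scale: scale1
- id: persimmon_seasonal
  category: food_item
  scale: scale1
- id: strawberry_seasonal
  category: food_item
  scale: scale1
- id: green_tea
  category: food_item
  scale: scale2
- id: black_tea_oolong_tea
  category: food_item
  scale: scale2
- id: coffee
  category: food_item
  scale: scale2
- id: cola_soft_drink
  category: food_item
  scale: scale2
- id: juice
  category: food_item
  scale: scale2
- id: rice
  category: food_item
  scale: scale3
- id: miso_soup
  category: food_item
  scale: scale3
- id: alcohol_frequency
  category: food_item
  scale: scale3
- id: sake
  category: food_item
  scale: scale4
- id: beer
  category: food_item
  scale: scale4
- id: shochu
  category: food_item
  scale: scale4
- id: whisky
  category: food_item
  scale: scale4
- id: wine
  category: food_item
  scale: scale4
- id: noodle_soup
  category: dietary_behavior
  scale: scale5
- id: seasoning_taste
  category: dietary_behavior
  scale: scale5
- id: meat_fat_preference
  category: dietary_behavior
  scale: scale5
- id: soy_sauce_amount
  category: dietary_behavior
  scale: scale5
- id: soy_sauce_frequency
  category: dietary_behavior
  scale: scale5
- id: side_dishes
  category: dietary_behavior
  scale: scale5
- id: rice_amount
  category: dietary_behavior
  scale: scale5
- id: eating_speed
  category: dietary_behavior
  scale: scale5
- id: breakfast
  category: dietary_behavior
  scale: scale3
- id: supplements
  category: dietary_behavior
  scale: scale1
- id: eating_habit_change
  category: dietary_behavior
  scale: scale6
- id: dietary_guidance
  category: dietary_behavior
  scale: scale6
- id: raw_fish
  category: cooking_method
  scale: scale1
- id: grilled_fish
  category: cooking_method
  scale: scale1
- id: boiled_fish
  category: cooking_method
  scale: scale1
- id: fried_fish
  category: cooking_method
  scale: scale1
- id: grilled_meat
  category: cooking_method
  scale: scale1
- id: hamburg_curry
  category: cooking_method
  scale: scale1
- id: deep_fried_meat
  category: cooking_method
  scale: scale1
- id: stir_fried_meat
  category: cooking_method
  scale: scale1
- id: stewed_meat
  category: cooking_method
  scale: scale1
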