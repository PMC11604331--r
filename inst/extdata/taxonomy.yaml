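# Default food-group taxonomy for branded-food snapshots.
#
# Groups follow the reformulation-monitor style categorisation used for the
# Dutch retail supply, with dairy and plant-based foods split into solid foods
# and beverages because the Nutri-Score algorithms differ between the two.
# Each group maps to exactly one scoring category and carries a default
# estimate of the fruits/vegetables/legumes content (percent), used when a
# product has no declared FVL value. The estimates are editable defaults, not
# measured values.
groups:
  - {key: bread_substitutes,     display: "Bread (substitutes)",              category: general_solid,        fvl_estimate: 0}
  - {key: cheeses,               display: "Cheeses",                          category: general_solid,        fvl_estimate: 0}
  - {key: baked_goods_pastries,  display: "Baked goods and pastries",         category: general_solid,        fvl_estimate: 0}
  - {key: sweets_sweet_goods,    display: "Sweets and sweet goods",           category: general_solid,        fvl_estimate: 0}
  - {key: breakfast_cereals,     display: "Breakfast cereals",                category: general_solid,        fvl_estimate: 0}
  - {key: dairy_plant_solid,     display: "Dairy and plant-based solid foods", category: general_solid,       fvl_estimate: 0}
  - {key: dairy_plant_beverages, display: "Dairy and plant-based beverages",  category: beverage,             fvl_estimate: 0}
  - {key: meat_preserves,        display: "Meat preserves",                   category: general_solid,        fvl_estimate: 0}
  - {key: meat_substitutes,      display: "Meat substitutes",                 category: general_solid,        fvl_estimate: 20}
  - {key: processed_legumes,     display: "Processed legumes",                category: general_solid,        fvl_estimate: 80}
  - {key: vegetable_preserves,   display: "Vegetable preserves",              category: general_solid,        fvl_estimate: 90}
  - {key: fruit_preserves,       display: "Fruit preserves",                  category: general_solid,        fvl_estimate: 90}
  - {key: cold_cut_meats,        display: "Cold-cut meats",                   category: general_solid,        fvl_estimate: 0}
  - {key: cold_savoury_snacks,   display: "Cold savoury snacks",              category: general_solid,        fvl_estimate: 10}
  - {key: pizzas,                display: "Pizzas",                           category: general_solid,        fvl_estimate: 20}
  - {key: soups,                 display: "Soups",                            category: general_solid,        fvl_estimate: 40}
  - {key: sauces,                display: "Sauces",                           category: general_solid,        fvl_estimate: 20}
  - {key: savoury_spreads,       display: "Savoury spreads",                  category: general_solid,        fvl_estimate: 30}
  - {key: fats_oils,             display: "Fats and oils",                    category: fats_oils_nuts_seeds, fvl_estimate: 0}
  - {key: soft_drinks,           display: "Soft drinks",                      category: beverage,             fvl_estimate: 0}
  - {key: ready_meals,           display: "Ready meals",                      category: general_solid,        fvl_estimate: 30}
# Groups whose products are cheeses (protein points always counted for these
# under the solid-food algorithm).
cheese_groups: [cheeses]
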