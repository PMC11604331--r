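# Updated Nutri-Score scoring scheme: main algorithm for solid foods (2022
# revision) and beverage algorithm (2023 revision), transcribed from the
# official guideline tables published by Sante publique France and the
# International Scientific Committee of Nutri-Score.
#
# The grids are data, not code: edit here and re-validate with read_scheme().
#
# boundary_convention decides which side of a cutoff earns a point:
#   inclusive: value >= cutoff earns the point. Package default; this is the
#              convention under which lowering sugars from 17 to 13.5 g/100 g
#              on the general-solid grid removes two points.
#   strict:    value > cutoff earns the point (the literal reading of the
#              official interval tables, ">x to <=y"; 17 -> 13.5 g then
#              removes one point).
name: nutriscore-updated-2023
boundary_convention: inclusive
categories:
  general_solid:
    grids:
      energy:
        unit: kJ/100g
        max_points: 10
        cutoffs: [335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350]
      sugars:
        unit: g/100g
        max_points: 15
        cutoffs: [3.4, 6.8, 10, 14, 17, 20, 24, 27, 31, 34, 37, 41, 44, 48, 51]
      sfa:
        unit: g/100g
        max_points: 10
        cutoffs: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
      salt:
        unit: g/100g
        max_points: 20
        cutoffs: [0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0,
                  2.2, 2.4, 2.6, 2.8, 3.0, 3.2, 3.4, 3.6, 3.8, 4.0]
      protein:
        unit: g/100g
        max_points: 7
        cutoffs: [2.4, 4.8, 7.2, 9.6, 12, 14, 17]
      fibre:
        unit: g/100g
        max_points: 5
        cutoffs: [3.0, 4.1, 5.2, 6.3, 7.4]
    fvl:
      unit: percent
      cutoffs: [40, 60, 80]
      points: [0, 1, 2, 5]
    # Protein points are dropped when negative points reach the threshold,
    # except for cheeses (the updated main algorithm keeps only the cheese
    # exemption; the pre-2022 fruit/vegetable exemption no longer applies).
    protein_rule:
      negative_threshold: 11
      cheese_exempt: true
    red_meat_protein_cap: 2
    class_bounds:
      A: [-.inf, 0]
      B: [1, 2]
      C: [3, 10]
      D: [11, 18]
      E: [19, .inf]
  fats_oils_nuts_seeds:
    grids:
      energy:
        unit: kJ/100g
        max_points: 10
        cutoffs: [120, 240, 360, 480, 600, 720, 840, 960, 1080, 1200]
      sugars:
        unit: g/100g
        max_points: 15
        cutoffs: [3.4, 6.8, 10, 14, 17, 20, 24, 27, 31, 34, 37, 41, 44, 48, 51]
      # Saturated fat is scored as the SFA / total fat ratio, in percent.
      sfa_fat_ratio:
        unit: percent
        max_points: 10
        cutoffs: [10, 16, 22, 28, 34, 40, 46, 52, 58, 64]
      salt:
        unit: g/100g
        max_points: 20
        cutoffs: [0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0,
                  2.2, 2.4, 2.6, 2.8, 3.0, 3.2, 3.4, 3.6, 3.8, 4.0]
      protein:
        unit: g/100g
        max_points: 7
        cutoffs: [2.4, 4.8, 7.2, 9.6, 12, 14, 17]
      fibre:
        unit: g/100g
        max_points: 5
        cutoffs: [3.0, 4.1, 5.2, 6.3, 7.4]
    fvl:
      unit: percent
      cutoffs: [40, 60, 80]
      points: [0, 1, 2, 5]
    protein_rule:
      negative_threshold: 7
      cheese_exempt: false
    class_bounds:
      A: [-.inf, -6]
      B: [-5, 2]
      C: [3, 10]
      D: [11, 18]
      E: [19, .inf]
  beverage:
    grids:
      energy:
        unit: kJ/100mL
        max_points: 10
        cutoffs: [30, 90, 150, 210, 240, 270, 300, 330, 360, 390]
      sugars:
        unit: g/100mL
        max_points: 10
        cutoffs: [0.5, 2, 3.5, 5, 6, 7, 8, 9, 10, 11]
      sfa:
        unit: g/100mL
        max_points: 10
        cutoffs: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
      salt:
        unit: g/100mL
        max_points: 20
        cutoffs: [0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4, 1.6, 1.8, 2.0,
                  2.2, 2.4, 2.6, 2.8, 3.0, 3.2, 3.4, 3.6, 3.8, 4.0]
      protein:
        unit: g/100mL
        max_points: 7
        cutoffs: [1.2, 1.5, 1.8, 2.1, 2.4, 2.7, 3.0]
      fibre:
        unit: g/100mL
        max_points: 5
        cutoffs: [3.0, 4.1, 5.2, 6.3, 7.4]
    fvl:
      unit: percent
      cutoffs: [40, 60, 80]
      points: [0, 2, 4, 6]
    # Beverages containing non-nutritive sweeteners receive extra
    # unfavourable points.
    sweetener_points: 4
    # Protein points always count for beverages.
    protein_rule:
      negative_threshold: .inf
      cheese_exempt: false
    # Class A is reserved for mineral waters (water rule), so the numeric
    # bounds start at B.
    class_bounds:
      B: [-.inf, 2]
      C: [3, 6]
      D: [7, 9]
      E: [10, .inf]
keywords:
  # Case-insensitive, diacritic-folded substring matching against product
  # name + ingredient text. Dutch and English terms (branded-food snapshots
  # carry Dutch labels).
  red_meat:
    - rundvlees
    - rund
    - varkensvlees
    - varken
    - kalfsvlees
    - kalf
    - lamsvlees
    - lam
    - geitenvlees
    - beef
    - pork
    - veal
    - lamb
    - goat meat
    - bacon
    - spek
    - ham
    - salami
    - chorizo
    - cervelaat
    - frankfurter
    - rookworst
    - gehakt
  sweeteners:
    - aspartaam
    - aspartame
    - acesulfaam
    - acesulfame
    - sucralose
    - sacharine
    - saccharin
    - cyclamaat
    - cyclamate
    - steviolglycosiden
    - steviol
    - stevia
    - neotaam
    - neotame
    - advantaam
    - advantame
    - zoetstof
    - e950
    - e951
    - e952
    - e954
    - e955
    - e957
    - e959
    - e960
    - e961
    - e962
    - e969
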