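# MIND diet rubric: 15 food groups scored 0 / 0.5 / 1 from weekly (or daily,
# as declared) servings, transcribed from the instrument's published cutoffs.
# Beneficial groups: score 1 if intake >= full_cutoff, 0.5 if >= half_cutoff.
# Detrimental groups: score 1 if intake < full_cutoff, 0.5 if < half_cutoff.
# Wine is window-scored: full credit only inside full_range (~1 glass/day),
# half credit inside half_range, 0 otherwise.  Total range 0-15.
instrument: MIND
version: 1
components:
  - name: green_leafy_vegetables
    column: green_leafy_srv_wk
    unit: servings/week
    direction: beneficial
    rule: three_level
    half_cutoff: 2
    full_cutoff: 6
  - name: other_vegetables      # excludes potatoes and potato products
    column: other_veg_srv_wk
    unit: servings/week
    direction: beneficial
    rule: three_level
    half_cutoff: 5
    full_cutoff: 7
  - name: berries
    column: berries_srv_wk
    unit: servings/week
    direction: beneficial
    rule: three_level
    half_cutoff: 1
    full_cutoff: 2
  - name: nuts
    column: nuts_srv_wk
    unit: servings/week
    direction: beneficial
    rule: three_level
    half_cutoff: 0.25
    full_cutoff: 5
  - name: olive_oil             # primary oil used; effectively binary
    column: oliveoil_srv_d
    unit: servings/day
    direction: beneficial
    rule: three_level
    half_cutoff: 1
    full_cutoff: 1
  - name: butter_margarine
    column: butter_marg_srv_d
    unit: servings/day
    direction: detrimental
    rule: three_level
    half_cutoff: 2
    full_cutoff: 1
  - name: cheese
    column: cheese_srv_wk
    unit: servings/week
    direction: detrimental
    rule: three_level
    half_cutoff: 7
    full_cutoff: 1
  - name: whole_grains
    column: wholegrain_srv_d
    unit: servings/day
    direction: beneficial
    rule: three_level
    half_cutoff: 1
    full_cutoff: 3
  - name: fish_not_fried
    column: fish_srv_wk
    unit: servings/week
    direction: beneficial
    rule: three_level
    half_cutoff: 0.25
    full_cutoff: 1
  - name: beans
    column: beans_srv_wk
    unit: servings/week
    direction: beneficial
    rule: three_level
    half_cutoff: 1
    full_cutoff: 3
  - name: poultry_not_fried
    column: poultry_srv_wk
    unit: servings/week
    direction: beneficial
    rule: three_level
    half_cutoff: 1
    full_cutoff: 2
  - name: red_meat_products
    column: redmeat_srv_wk
    unit: servings/week
    direction: detrimental
    rule: three_level
    half_cutoff: 7
    full_cutoff: 4
  - name: fast_fried_food
    column: fastfried_srv_wk
    unit: servings/week
    direction: detrimental
    rule: three_level
    half_cutoff: 4
    full_cutoff: 1
  - name: pastries_sweets
    column: pastries_srv_wk
    unit: servings/week
    direction: detrimental
    rule: three_level
    half_cutoff: 7
    full_cutoff: 5
  - name: wine
    column: wine_srv_wk
    unit: servings/week
    direction: moderate
    rule: three_level_window
    half_range: [1, 6]
    full_range: [6, 8]
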