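# Mediterranean diet score (MDS) rubric: nine components scored 0/1 against
# within-sample medians of visit-averaged intake; alcohol scored by a
# sex-specific moderate window.  Total range 0-9.
instrument: MDS
version: 1
components:
  - name: vegetables
    column: veg_srv_d
    unit: servings/day
    direction: beneficial
    rule: median_split
  - name: legumes
    column: legume_srv_d
    unit: servings/day
    direction: beneficial
    rule: median_split
  - name: fruits_nuts
    column: fruit_srv_d
    unit: servings/day
    direction: beneficial
    rule: median_split
  - name: whole_grains
    column: wholegrain_srv_d
    unit: servings/day
    direction: beneficial
    rule: median_split
  - name: fish
    column: fish_srv_wk
    unit: servings/week
    direction: beneficial
    rule: median_split
  - name: mufa_sfa_ratio
    column: mufa_sfa_ratio
    unit: ratio
    direction: beneficial
    rule: median_split
  - name: meat
    column: meat_srv_d
    unit: servings/day
    direction: detrimental
    rule: median_split
  - name: dairy
    column: dairy_srv_d
    unit: servings/day
    direction: detrimental
    rule: median_split
  - name: alcohol
    column: alcohol_g_d
    unit: g/day
    direction: moderate
    rule: moderate_window
    window:
      female: [5.0, 25.0]
      male: [10.0, 50.0]
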