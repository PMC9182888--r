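# AHEI-2010 rubric: 11 components, each scored proportionally 0-10 by linear
# interpolation between anchor_zero (0 points) and anchor_full (10 points),
# clamped outside the anchors.  Detrimental components simply have
# anchor_zero > anchor_full.  Alcohol is window-scored: 10 points inside the
# sex-specific moderate window, abstainer_score for zero intake, 0 points at
# or beyond zero_anchor, linear in between.  Total range 0-110.  Anchors
# transcribed from the published index; sodium anchors are fixed values
# approximating the instrument's intake deciles.
instrument: AHEI
version: 1
components:
  - name: vegetables
    column: veg_srv_d
    unit: servings/day
    direction: beneficial
    rule: proportional
    anchor_zero: 0
    anchor_full: 5
  - name: fruit
    column: fruit_srv_d
    unit: servings/day
    direction: beneficial
    rule: proportional
    anchor_zero: 0
    anchor_full: 4
  - name: whole_grains
    column: wholegrain_g_d
    unit: g/day
    direction: beneficial
    rule: proportional
    anchor_zero: 0
    anchor_full:
      female: 75
      male: 90
  - name: ssb_fruit_juice
    column: ssb_juice_srv_d
    unit: servings/day
    direction: detrimental
    rule: proportional
    anchor_zero: 1
    anchor_full: 0
  - name: nuts_legumes
    column: nut_legume_srv_d
    unit: servings/day
    direction: beneficial
    rule: proportional
    anchor_zero: 0
    anchor_full: 1
  - name: red_processed_meat
    column: red_proc_meat_srv_d
    unit: servings/day
    direction: detrimental
    rule: proportional
    anchor_zero: 1.5
    anchor_full: 0
  - name: trans_fat
    column: trans_pct_energy
    unit: percent energy
    direction: detrimental
    rule: proportional
    anchor_zero: 4
    anchor_full: 0.5
  - name: longchain_n3
    column: longchain_n3_mg_d
    unit: mg/day (EPA+DHA)
    direction: beneficial
    rule: proportional
    anchor_zero: 0
    anchor_full: 250
  - name: pufa
    column: pufa_pct_energy
    unit: percent energy
    direction: beneficial
    rule: proportional
    anchor_zero: 2
    anchor_full: 10
  - name: sodium
    column: sodium_mg_d
    unit: mg/day
    direction: detrimental
    rule: proportional
    anchor_zero: 5000
    anchor_full: 1500
  - name: alcohol
    column: alcohol_drinks_d
    unit: drinks/day
    direction: moderate
    rule: moderate_window
    window:
      female: [0.5, 1.5]
      male: [0.5, 2.0]
    zero_anchor:
      female: 2.5
      male: 3.5
    abstainer_score: 2.5
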