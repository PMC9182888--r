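# 44-item deficit-accumulation frailty index map.
# Rules:
#   ordinal5  - integer codes 0..4 (none .. unable/poor) mapped to
#               {0, 0.25, 0.5, 0.75, 1}
#   binary    - 0/1 indicator taken as the deficit score
#   threshold - indicator derived within-sample by derive_threshold_deficits()
# The ordinal codings for ADL/IADL difficulty, SF-12 self-rated health and the
# threshold cutoff conventions are declared approximations of the source
# instruments; edit this file to match a cohort's own coding scheme.
version: 1
items:
  # 15 ADL / IADL difficulty items
  - {name: adl_walk_steps,      column: adl_walk_steps,      rule: ordinal5}
  - {name: adl_lift_carry,      column: adl_lift_carry,      rule: ordinal5}
  - {name: adl_bed_chair,       column: adl_bed_chair,       rule: ordinal5}
  - {name: adl_bathing,         column: adl_bathing,         rule: ordinal5}
  - {name: adl_dressing,        column: adl_dressing,        rule: ordinal5}
  - {name: adl_eating,          column: adl_eating,          rule: ordinal5}
  - {name: adl_toileting,       column: adl_toileting,       rule: ordinal5}
  - {name: adl_walk_room,       column: adl_walk_room,       rule: ordinal5}
  - {name: iadl_heavy_house,    column: iadl_heavy_house,    rule: ordinal5}
  - {name: iadl_prepare_meals,  column: iadl_prepare_meals,  rule: ordinal5}
  - {name: iadl_shopping,       column: iadl_shopping,       rule: ordinal5}
  - {name: iadl_telephone,      column: iadl_telephone,      rule: ordinal5}
  - {name: iadl_medication,     column: iadl_medication,     rule: ordinal5}
  - {name: iadl_finances,       column: iadl_finances,       rule: ordinal5}
  - {name: incontinence,        column: incontinence,        rule: ordinal5}
  # self-rated health (SF-12 item, excellent..poor -> 0..1)
  - {name: self_rated_health,   column: self_rated_health,   rule: ordinal5}
  # 5 CES-D items (coded as deficit indicators; "feeling happy" pre-reversed)
  - {name: cesd_depressed,      column: cesd_depressed,      rule: binary}
  - {name: cesd_effort,         column: cesd_effort,         rule: binary}
  - {name: cesd_get_going,      column: cesd_get_going,      rule: binary}
  - {name: cesd_lonely,         column: cesd_lonely,         rule: binary}
  - {name: cesd_not_happy,      column: cesd_not_happy,      rule: binary}
  # 4 MMSE items (1 = failed item)
  - {name: mmse_orient_time,    column: mmse_orient_time,    rule: binary}
  - {name: mmse_orient_place,   column: mmse_orient_place,   rule: binary}
  - {name: mmse_attention,      column: mmse_attention,      rule: binary}
  - {name: mmse_recall,         column: mmse_recall,         rule: binary}
  # 15 condition indicators
  - {name: cond_cancer,         column: cond_cancer,         rule: binary}
  - {name: cond_anemia,         column: cond_anemia,         rule: binary}
  - {name: cond_hypertension,   column: cond_hypertension,   rule: binary}
  - {name: cond_diabetes,       column: cond_diabetes,       rule: binary}
  - {name: cond_heart_disease,  column: cond_heart_disease,  rule: binary}
  - {name: cond_chf,            column: cond_chf,            rule: binary}
  - {name: cond_stroke,         column: cond_stroke,         rule: binary}
  - {name: cond_pad,            column: cond_pad,            rule: binary}
  - {name: cond_copd,           column: cond_copd,           rule: binary}
  - {name: cond_ckd,            column: cond_ckd,            rule: binary}
  - {name: cond_hip_replace,    column: cond_hip_replace,    rule: binary}
  - {name: cond_joint_pain,     column: cond_joint_pain,     rule: binary}
  - {name: cond_depression,     column: cond_depression,     rule: binary}
  - {name: cond_parkinsons,     column: cond_parkinsons,     rule: binary}
  - {name: cond_cognitive,      column: cond_cognitive,      rule: binary}
  # 4 within-sample threshold deficits
  - {name: weight_loss,         column: weight_loss,         rule: threshold}
  - {name: low_activity,        column: low_activity,        rule: threshold}
  - {name: slowness,            column: slowness,            rule: threshold}
  - {name: weakness,            column: weakness,            rule: threshold}
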