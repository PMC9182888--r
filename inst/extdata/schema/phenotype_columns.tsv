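column	type
participant_id	character
age	numeric
sex	character
height_m	numeric
weight_kg	numeric
bmi	numeric
egfr	numeric
walk_speed_m_s	numeric
grip_kg	numeric
phys_activity	numeric
weight_change_frac	numeric
adl_walk_steps	integer 0-4
adl_lift_carry	integer 0-4
adl_bed_chair	integer 0-4
adl_bathing	integer 0-4
adl_dressing	integer 0-4
adl_eating	integer 0-4
adl_toileting	integer 0-4
adl_walk_room	integer 0-4
iadl_heavy_house	integer 0-4
iadl_prepare_meals	integer 0-4
iadl_shopping	integer 0-4
iadl_telephone	integer 0-4
iadl_medication	integer 0-4
iadl_finances	integer 0-4
incontinence	integer 0-4
self_rated_health	integer 0-4
cesd_depressed	integer 0/1
cesd_effort	integer 0/1
cesd_get_going	integer 0/1
cesd_lonely	integer 0/1
cesd_not_happy	integer 0/1
mmse_orient_time	integer 0/1
mmse_orient_place	integer 0/1
mmse_attention	integer 0/1
mmse_recall	integer 0/1
cond_cancer	integer 0/1
cond_anemia	integer 0/1
cond_hypertension	integer 0/1
cond_diabetes	integer 0/1
cond_heart_disease	integer 0/1
cond_chf	integer 0/1
cond_stroke	integer 0/1
cond_pad	integer 0/1
cond_copd	integer 0/1
cond_ckd	integer 0/1
cond_hip_replace	integer 0/1
cond_joint_pain	integer 0/1
cond_depression	integer 0/1
cond_parkinsons	integer 0/1
cond_cognitive	integer 0/1
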