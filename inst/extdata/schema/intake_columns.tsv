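column	type	unit
participant_id	character	-
visit_id	integer	-
energy_kcal	numeric	kcal/day
veg_srv_d	numeric	servings/day
legume_srv_d	numeric	servings/day
fruit_srv_d	numeric	servings/day
wholegrain_srv_d	numeric	servings/day
wholegrain_g_d	numeric	g/day
fish_srv_wk	numeric	servings/week
mufa_g_d	numeric	g/day
sfa_g_d	numeric	g/day
meat_srv_d	numeric	servings/day
dairy_srv_d	numeric	servings/day
alcohol_g_d	numeric	g/day
green_leafy_srv_wk	numeric	servings/week
other_veg_srv_wk	numeric	servings/week
berries_srv_wk	numeric	servings/week
nuts_srv_wk	numeric	servings/week
oliveoil_srv_d	numeric	servings/day
butter_marg_srv_d	numeric	servings/day
cheese_srv_wk	numeric	servings/week
beans_srv_wk	numeric	servings/week
poultry_srv_wk	numeric	servings/week
redmeat_srv_wk	numeric	servings/week
fastfried_srv_wk	numeric	servings/week
pastries_srv_wk	numeric	servings/week
wine_srv_wk	numeric	servings/week
ssb_juice_srv_d	numeric	servings/day
nut_legume_srv_d	numeric	servings/day
red_proc_meat_srv_d	numeric	servings/day
trans_pct_energy	numeric	percent energy
longchain_n3_mg_d	numeric	mg/day
pufa_pct_energy	numeric	percent energy
sodium_mg_d	numeric	mg/day
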