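column,type,units,allowed,description
id,any,,,respondent identifier (generated if absent)
sex,character,,male|female,sex
age,integer,years,20-99,age at survey
smoking_status,character,,current|former|never,smoking status
cigs_per_day,numeric,cigarettes/day,>=0,daily amount (current: now; former: when smoking); empty for occasional/never
lifetime_cigs_lt_100,logical,,true|false,fewer than 100 cigarettes ever smoked
years_since_quit,numeric,years,>=0,time since quitting (former smokers)
drinks_last_week,numeric,drinks,>=0,total drinks in the previous week
max_drinks_any_day_last_week,numeric,drinks,>=0,most drinks on any single day in the previous week
weekly_binge,logical,,true|false,bingeing (5+ drinks on one occasion) on a weekly basis
mets_per_day,numeric,MET,>=0,daily averaged leisure-time metabolic equivalent
fruit_veg_freq_per_day,numeric,times/day,>=0,fruit and vegetable intake frequency excluding juice
juice_freq_per_day,numeric,times/day,>=0,fruit juice intake frequency
potato_freq_per_week,numeric,times/week,>=0,potato intake frequency
carrot_freq_per_week,numeric,times/week,>=0,carrot intake frequency
material_quintile,integer,,1-5,material deprivation quintile (1 least deprived)
social_quintile,integer,,1-5,social deprivation quintile (1 least deprived)
education,character,,lt_hs|hs_grad|post_sec,highest education attained
years_since_immigration,character,,gt45_or_born|0_15|16_30|31_45,years since immigration
heart_disease,logical,,true|false,physician-diagnosed coronary heart disease
stroke,logical,,true|false,physician-diagnosed stroke
cancer,logical,,true|false,physician-diagnosed cancer
diabetes,logical,,true|false,physician-diagnosed diabetes
bmi_ge_35,logical,,true|false,body mass index of 35 or more
weight,numeric,persons,>0,survey weight
followup_years,numeric,years,>=0,follow-up time (linked surveys only)
died,logical,,true|false,death during follow-up (linked surveys only)
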