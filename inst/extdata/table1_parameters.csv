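name,mean,se,dist,dsa_rule,se_kind,n_obs,units,source
prev_t2dm_30,0.0631,0.00002,beta,pct20,se,NA,proportion,national survey
prev_t2dm_35,0.0683,0.00003,beta,pct20,se,NA,proportion,national survey
prev_t2dm_40,0.0743,0.00004,beta,pct20,se,NA,proportion,national survey
prev_t2dm_45,0.0814,0.00005,beta,pct20,se,NA,proportion,national survey
sens_findrisc,0.864,0.082,beta,ci95,se,NA,proportion,literature
spec_findrisc,0.583,0.031,beta,ci95,se,NA,proportion,literature
sens_fcg,0.842,0.003,beta,ci95,se,NA,proportion,literature
spec_fcg,0.766,0.001,beta,ci95,se,NA,proportion,literature
sens_fpg,0.544,0.006,beta,ci95,se,NA,proportion,literature
spec_fpg,0.989,0.0004,beta,ci95,se,NA,proportion,literature
hba1c_undx,8.5,2.5,normal,ci95,se,NA,percent,literature
hba1c_dx,7.0,1.5,normal,ci95,se,NA,percent,literature
hba1c_comp,9.1,2.4,normal,ci95,se,NA,percent,literature
rr_death_t2dm,1.89,0.077,lognormal,ci95,se,NA,ratio,literature
rr_death_per_hba1c,1.38,0.048,lognormal,ci95,se,NA,ratio,literature
rr_comp_per_hba1c,1.40,0.036,lognormal,ci95,se,NA,ratio,literature
p_ngt_undx,0.0067,0.0011,beta,pct20,se,NA,annual probability,literature
p_ngt_dx,0.0067,0.0011,beta,pct20,se,NA,annual probability,literature
p_undx_dx,0.0352,0.0102,beta,pct20,se,NA,annual probability,literature
p_undx_comp,0.0231,0.000001,beta,pct20,se,NA,annual probability,estimated
p_dx_comp,0.0140,0.000001,beta,pct20,se,NA,annual probability,literature
cost_test_findrisc,0.3,0,fixed,pct20,se,NA,USD,estimated
cost_test_fcg,0.7,0,fixed,pct20,se,NA,USD,price list
cost_test_fpg,0.9,0,fixed,pct20,se,NA,USD,price list
cost_med_dx,66.0,76945,gamma,pct20,variance,1631,USD per year,primary data
cost_med_undx,17.9,0,fixed,pct20,se,NA,USD per year,assumed
cost_med_comp,160.1,86476,gamma,pct20,variance,1631,USD per year,primary data
cost_nonmed_screen_chs,0.6,0,fixed,pct20,se,NA,USD per visit,estimated
cost_nonmed_screen_dhc,1.96,0,fixed,pct20,se,NA,USD per visit,estimated
cost_nonmed_dx,228.1,684856,gamma,pct20,variance,218,USD per year,primary data
cost_nonmed_undx,99.6,0,fixed,pct20,se,NA,USD per year,assumed
cost_nonmed_comp,327.1,189641,gamma,pct20,variance,218,USD per year,primary data
u_ngt,0.91,0.0038,beta,ci95,se,NA,utility,literature
u_undx,0.91,0.0038,beta,ci95,se,NA,utility,assumed
u_dx,0.89,0.02,beta,ci95,se,NA,utility,primary data
u_comp,0.63,0.02,beta,ci95,se,NA,utility,primary data
adherence_referral,1.0,0,fixed,none,se,NA,proportion,default
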