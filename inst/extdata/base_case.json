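{"arms":{"five_grass":{"name":"five_grass","label":"5-grass tablet","rtss":3.26,"disc_y1":0.29,"disc_y2":0.28,"drug_cost_per_month":100.004761904762,"drug_cost_annual_fixed":0,"visits_per_treatment_year":3.43154406,"injections_per_treatment_year":0,"supervised_first_dose":true,"diagnostic_in_year1":true},"allergoid":{"name":"allergoid","label":"Allergoid mix","rtss":3.64,"disc_y1":0.41,"disc_y2":0.34,"drug_cost_per_month":0,"drug_cost_annual_fixed":483.2,"visits_per_treatment_year":5.14744688,"injections_per_treatment_year":8.07011983,"supervised_first_dose":false,"diagnostic_in_year1":true},"symptomatic":{"name":"symptomatic","label":"Symptomatic treatment","rtss":4.47,"disc_y1":0,"disc_y2":0,"drug_cost_per_month":0,"drug_cost_annual_fixed":0,"visits_per_treatment_year":0,"injections_per_treatment_year":0,"supervised_first_dose":false,"diagnostic_in_year1":false}},"clinical":{"p_asthma_symptomatic":0.0046,"rr_asthma_ait":0.505,"p_death_all":0.00046,"p_death_asthma":0.00069,"mean_age_entry":29},"utility":{"u_baseline":0.96997356,"k_rtss_slope":0.05908002,"season_months":3,"asthma_decrement":0,"eq5d_ait":0.976,"eq5d_symptomatic":0.947},"costs":{"c_specialist_visit":13.29,"c_visit_additional":3.69,"c_injection":5.11,"c_diagnostics":20.61,"c_asthma_annual":186.3,"c_loratadine_ait":5.14,"c_budesonide_ait":2.19,"c_loratadine_sympt":7.54,"c_budesonide_sympt":3.83,"visits_per_year_off_treatment":1.9,"c_labour_hour":30.7,"sick_days_symptomatic":3.7,"sick_days_ait":1.2,"productivity_saving_per_season":133.28842},"settings":{"horizon_years":9,"cycle_length":1,"discount_rate":0.03,"wtp_grid":[0,1000,2000,3000,4000,5000,6000,7000,8000,9000,10000,11000,12000,13000,14000,15000,16000,17000,18000,19000,20000,21000,22000,23000,24000,25000,26000,27000,28000,29000,30000,31000,32000,33000,34000,35000,36000,37000,38000,39000,40000,41000,42000,43000,44000,45000,46000,47000,48000,49000,50000],"n_psa":1000,"rng_seed":1,"perspective":"payer","efficacy_se_scale":0.15336}}
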