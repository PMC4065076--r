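sex,p_drinkers,mean_dose_gday,q1_median_gday,q4_median_gday,source_year_prevalence,source_year_dose
male,0.7767042798750055,28.53,2.80,56.0,1989,1998
female,0.2332151328111294,6.38,0.80,28.0,1989,1998
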