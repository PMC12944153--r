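label,study,age_min,age_max,prop_female,dose_mg,interval_h,n_doses,duration_h,window,obs_cmax_mean,obs_cmax_sd,obs_auc_mean,obs_auc_sd,role
bahrami_100mg_sd,Bahrami et al.,24,30,0,100,24,1,120,0-inf,46.2,29.0,1308,781,calibration
orlando_50mg_sd_elderly,Orlando et al.,66,80,0,50,24,1,120,0-96,31,19,885,560,verification
fleishaker_50mg_sd,Fleishaker et al.,20,44,0,50,24,1,96,0-24,21.5,4.9,328.0,84.6,verification
fleishaker_100mg_qd,Fleishaker et al.,20,44,0,100,24,14,NA,ss,99.3,35.0,1762,737,verification
spigset_50mg_bid,Spigset et al.,23,34,0,50,12,28,NA,ss,77.7,31.2,761.1,302.2,verification
spigset_100mg_bid,Spigset et al.,23,34,0,100,12,28,NA,ss,234.9,100.0,2401.4,1031.1,verification
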