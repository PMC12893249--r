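stat,duration_min,n_triggers,n_ieds,n_incorrect_normal,n_missed_normal,n_correct_ied,n_incorrect_ied,n_missed_ied,p_incorrect_normal_pct,p_missed_normal_pct,p_incorrect_ied_pct,p_missed_ied_pct,p_incorrect_due_ied_pct,p_missed_due_ied_pct,sensitivity,specificity,fp_rate_per_min
mean,23.5,67.5,23.1,.4,.1,22.4,.5,.5,.5,.0,2.3,3.0,1.8,3.0,.85,.99,2.2
sd,10.8,30.6,21.9,.8,.3,21.9,.7,1.1,1.0,.0,4.0,6.8,3.8,6.8,.14,.00,.9
count,13,13,13,12,12,13,13,13,13,13,13,13,13,13,12,13,13
median,23.0,66.0,12.0,.0,.0,12.0,.0,.0,.0,.0,.0,.0,.0,.0,.90,.99,2.1
ci_low,,,,,,,,,0,0,0,0,0,0,.80,.99,1.5
ci_high,,,,,,,,,1,0,7,3,7,3,.96,.99,3.2
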