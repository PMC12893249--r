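stat,duration_min,n_triggers,n_ieds,mean_rt_normal_ms,delta_rt_ms,ied_dur_no_crash_ms,n_crashes_ied,ied_dur_crash_ms,n_crashes_normal,p_crash_ied_pct,p_crash_normal_pct,p_crash_due_ied_pct,cum_crash_risk_pct,sensitivity,specificity,fp_rate_per_min
mean,20.4,137.9,44.6,547.3,49.5,1297.8,2.6,2629.1,1.9,8.0,3.7,4.3,8.7,.86,.98,4.2
sd,8.4,113.3,36.8,87.1,32.9,445.4,3.4,2808.1,3.2,13.2,8.7,7.1,10.6,.13,.01,3.5
count,19,19,19,18,18,18,18,14,18,18,18,18,18,18,18,19
median,21.0,78.0,44.0,565.4,43.8,1237.5,1.0,1640.0,1.0,2.7,.9,.9,5.7,.90,.99,2.8
ci_low,,,,,20.3,880,,1307,,0,0,0,1.9,.81,.98,2.1
ci_high,,,,,64.7,1709,,3194,,10.0,3.2,6.0,10.7,.95,.99,5.9
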