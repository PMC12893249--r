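patient,duration_min,n_triggers,n_ieds,mean_rt_normal_ms,delta_rt_ms,ied_dur_no_crash_ms,n_crashes_ied,ied_dur_crash_ms,n_crashes_normal,p_crash_ied_pct,p_crash_normal_pct,p_crash_due_ied_pct,cum_crash_risk_pct,sensitivity,specificity,fp_rate_per_min
1,26,73,44,428.0,60.7,1853,4,2892,1,10.0,3.4,6.6,8.0,0.86,0.99,2.8
2,8,78,49,356.1,78.4,1709,1,3194,0,2.0,0,2.0,10.7,0.90,0.99,2.1
3,12,178,72,476.9,18.3,1358,0,716,0,0.0,0,0.0,0.8,0.89,0.99,2.3
4,14,61,29,627.6,39.2,671,1,1307,1,3.4,3.2,0.2,2.9,0.95,0.99,2.6
5,16,135,26,480.8,20.3,859,0,,0,0.0,0,0.0,0.9,0.83,0.97,5.9
6,36,246,51,474.2,56.5,1210,2,12367,0,3.9,0,3.9,6.7,0.91,0.99,2.8
7,21,123,17,547.9,135.1,1697,5,3313,2,29.4,1.9,27.5,43.1,0.81,0.99,2.8
8,23,77,0,621.3,,,,,,,,,,,0.98,3.5
9,26,12,76,554.5,10.4,880,1,1775,1,1.3,0.8,0.5,0.4,0.67,0.99,0.5
10,20,51,1,574.0,32.3,1140,0,,0,0.0,0,0.0,1.9,1.00,0.99,1.8
11,28,425,97,564.7,48.3,1201,1,1061,3,1.0,0.9,0.1,4.6,0.97,0.94,9.7
12,9,205,112,593.2,59.7,2125,13,2293,5,11.6,5.6,6.0,7.7,0.57,0.99,9.3
13,14,305,104,747.4,4.7,1265,1,1373,1,1.0,0.5,0.5,0.2,0.99,0.95,14.0
14,21,111,45,612.9,64.7,1809,2,1339,2,4.4,3.1,1.3,9.3,0.95,0.99,2.7
15,30,65,1,566.1,36.9,664,0,,0,0.0,0,0.0,2.6,1.00,0.99,2.1
16,21,53,15,587.7,20.0,1842,8,2185,14,53.3,38.9,14.4,14.4,0.79,0.99,1.7
17,18,31,5,504.9,71.4,741,1,1488,1,16.6,4.5,12.1,12.1,0.60,0.99,1.3
18,9,49,11,607.1,29.5,903,0,,1,0,2.9,-2.9,2.5,0.83,0.98,3.6
19,,,,,,,,,,,,,,,,
20,35,343,93,481.1,105.1,1434,6,1505,2,6.5,0.8,5.7,27.4,0.91,0.97,6.9
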