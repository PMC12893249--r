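patient,duration_min,n_triggers,n_ieds,n_incorrect_normal,n_missed_normal,n_correct_ied,n_incorrect_ied,n_missed_ied,p_incorrect_normal_pct,p_missed_normal_pct,p_incorrect_ied_pct,p_missed_ied_pct,p_incorrect_due_ied_pct,p_missed_due_ied_pct,sensitivity,specificity,fp_rate_per_min
1,,,,,,,,,,,,,,,,,
2,10,66,51,0,0,50,1,0,0.0,0.0,1.9,0.0,1.9,0.0,0.94,0.99,1.5
3,,,,,,,,,,,,,,,,,
4,,,,,,,,,,,,,,,,,
5,9,25,4,0,0,4,0,0,0.0,0.0,0.0,0.0,0.0,0.0,0.80,0.99,2.3
6,21,91,10,2,1,7,2,4,2.6,0.0,12.5,25.0,9.9,25.0,0.88,0.98,4.1
7,16,45,12,0,0,10,1,1,0.0,0.0,8.3,8.3,8.3,8.3,0.82,0.99,2.1
8,29,73,1,1,0,1,0,0,1.4,0.0,0.0,0.0,-1.4,0.0,0.50,0.99,2.5
9,26,33,21,0,0,21,0,0,0,0,0,0,0,0.0,0.63,0.99,0.5
10,52,61,0,0,0,0,0,0,0,0.0,0,0.0,0.0,0.0,,0.99,1.2
11,23,140,60,2,0,59,0,1,2.8,0,0,1.7,-2.8,1.7,0.96,0.99,3.5
12,,,,,,,,,,,,,,,,,
13,20,105,67,0,0,67,0,0,0,0,0,0,0,0.0,0.98,0.99,1.9
14,29,79,29,0,0,29,0,1,0,0,0,3.4,0,3.4,0.93,0.99,1.6
15,31,33,12,0,0,12,0,0,0,0,0,0,0,0,0.91,0.98,1.7
16,,,,,,,,,,,,,,,,,
17,,,,,,,,,,,,,,,,,
18,,,,,,,,,,,,,,,,,
19,26,66,5,0,0,5,0,0,0,0,0,0,0,0.0,0.83,0.99,2.3
20,13,60,28,0,0,26,2,0,0,0,7.1,0,7.1,0.0,1,0.99,3.2
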