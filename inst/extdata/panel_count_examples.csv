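table,cancer,dataset,approach,variant,n_probes,target_pos,target_neg,paired_pos,paired_neg,other_ts_pos,other_ts_neg,other_all_pos,other_all_neg,total_n,printed_sensitivity,printed_cancer_specificity,printed_ts_specificity,printed_all_samples_specificity,printed_accuracy
T1,LIHC,identification,non-clustered,primary,6,344,33,0,50,116,2116,119,2357,2853,91.2,100.0,94.8,95.2,94.7
T1,LIHC,identification,clustered,primary,8,336,41,1,49,61,2171,62,2413,2853,89.1,98.0,97.3,97.5,96.4
T1,LIHC,verification,non-clustered,primary,6,112,2,0,48,51,253,66,602,782,98.2,100.0,83.3,90.1,91.3
T1,LIHC,verification,clustered,primary,8,110,4,4,44,18,286,24,644,782,96.5,91.7,94.1,96.4,96.4
T2,CHOL,identification,non-clustered,primary,3,28,8,0,9,235,2338,235,2582,2853,77.8,100.0,90.9,91.7,91.5
T2,CHOL,identification,clustered,primary,4,26,10,0,9,189,2384,195,2622,2853,72.2,100.0,92.7,93.1,92.8
T2,CHOL,verification,non-clustered,primary,3,69,47,0,16,39,263,69,597,782,59.5,100.0,87.1,89.6,85.2
T2,CHOL,verification,clustered,primary,4,83,33,0,16,5,297,13,653,782,71.6,100.0,98.3,98.0,94.1
T3,CRC,identification,non-clustered,primary,4,371,16,0,45,199,2023,199,2267,2853,95.9,100.0,91.0,91.9,92.5
T3,CRC,identification,clustered,primary,3,243,144,0,45,56,2166,56,2410,2853,62.8,100.0,97.5,97.7,93.0
T3,CRC,verification,non-clustered,primary,4,82,7,10,71,26,303,41,652,782,92.1,87.7,92.1,94.1,93.9
T3,CRC,verification,clustered,primary,3,51,38,0,81,2,327,2,691,782,57.3,100.0,99.4,99.7,94.6
T4,LUAD,identification,non-clustered,primary,2,358,96,32,0,207,1948,241,2126,2853,78.9,0.0,90.4,89.8,88.5
T4,LUAD,verification,non-clustered,primary,2,6,3,28,0,49,360,78,695,782,66.7,0.0,88.0,89.9,89.6
T4,LUAD,verification,clustered,primary,7,3,6,0,28,3,406,22,751,782,33.3,100.0,99.3,97.2,96.4
T5,PAAD,identification,non-clustered,primary,2,152,32,8,2,374,2051,379,2282,2853,82.6,20.0,84.6,85.8,85.3
T5,PAAD,identification,clustered,primary,4,131,53,8,2,87,2338,97,2564,2853,71.2,20.0,96.4,96.1,94.5
T5,PAAD,verification,non-clustered,primary,2,15,0,3,0,69,334,88,679,782,100.0,0.0,82.9,88.7,88.9
T5,PAAD,verification,clustered,primary,4,13,2,3,0,19,384,27,740,782,86.7,0.0,95.3,96.5,96.3
T6,STAD,identification,non-clustered,primary,5,356,39,0,2,198,2016,238,2220,2853,90.1,100.0,94.1,90.3,90.3
T6,STAD,identification,clustered,primary,7,291,104,0,2,138,2076,209,2249,2853,73.7,100.0,93.8,91.5,89.0
T6,STAD,verification,non-clustered,primary,5,22,2,0,84,19,375,19,739,782,91.7,100.0,95.2,97.5,97.3
T6,STAD,verification,clustered,primary,7,17,7,0,84,25,369,31,727,782,70.8,100.0,93.7,95.9,95.1
T7,BRCA,identification,non-clustered,primary,7,690,86,3,93,109,1724,110,1964,2853,88.9,96.9,94.1,94.7,93.0
T7,BRCA,identification,clustered,primary,10,712,64,5,91,173,1660,173,1899,2853,91.8,94.8,90.6,91.4,91.5
T7,BRCA,verification,non-clustered,primary,7,43,8,0,104,33,334,35,696,782,84.3,100.0,91.0,95.2,94.5
T7,BRCA,verification,clustered,primary,10,44,7,2,102,17,350,19,712,782,86.3,98.1,95.4,97.4,96.7
T8,PAAD,verification,non-clustered,metastasis,2,13,0,3,15,88,350,107,695,813,100.0,83.3,79.8,86.8,86.8
T8,PAAD,verification,clustered,metastasis,4,9,4,1,17,33,404,41,760,813,69.2,94.4,92.4,94.9,94.5
T8,BRCA,verification,non-clustered,metastasis,7,15,3,4,9,80,352,82,714,813,83.3,69.2,81.4,89.7,89.5
T8,BRCA,verification,clustered,metastasis,9,15,3,0,13,61,371,63,733,813,83.3,100.0,85.8,92.1,91.9
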