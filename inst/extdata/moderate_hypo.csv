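study,author,n,brfs_5y,total_dose,n_fractions,dose_per_fraction,c,definition,risk_group,subset_of_pooled
1,Arcangeli,83,0.85,62,20,,192.2,Phoenix,,
2,Catton,608,0.85,60,20,,180,Phoenix,,
3,Cheung,230,0.837,67.5,25,,182.25,Phoenix,,
4,Chin S,112,0.68,52.5,20,,137.8125,Phoenix,,
5,Dearnaley,1077,0.859,57,19,,171,Phoenix,,
5,Dearnaley,1074,0.906,60,20,,180,Phoenix,,
6,Di Muzio,80,0.911,74.2,28,,196.63,Phoenix,,
6,Di Muzio,78,0.946,71.4,28,,182.07,Phoenix,,
6,Di Muzio,53,0.962,74.2,28,,196.63,Phoenix,,
7,Faria,82,0.954,66,22,,198,Phoenix,,
8,Fonteyne,113,0.94,56,16,,196,Phoenix,,
9,Hashimoto,195,0.924,66,22,,198,Phoenix,,
10,Lieng,96,0.81,60,20,,180,Phoenix,,
10,Lieng,27,0.88,66,22,,198,Phoenix,,
11,Incrocci,407,0.805,64.6,19,,219.64,Phoenix,,
12,Kim,30,0.929,70,28,,175,Phoenix,,
13,Kuban,102,0.96,72,30,,172.8,ASTRO,,
14,Kupelian,100,0.88,70,28,,175,Phoenix,,
15,Kupelian,770,0.83,70,28,,175,Phoenix,,
16,Leborgne,114,0.894,61.2,20,,187.272,Phoenix,,
17,Mai,596,0.927,76.65,35,,167.8635,Phoenix,,
18,Patel,129,0.97,66,22,,198,Phoenix,,
19,Pervez,60,0.9167,67.5,25,,182.25,Phoenix,,
20,Pollack,151,0.81,70.2,26,,189.54,Phoenix,,
21,Shimizu,73,0.77,74.8,34,,164.56,Phoenix,,
21,Shimizu,21,0.92,74.8,34,,164.56,Phoenix,,
21,Shimizu,44,0.95,72.6,33,,159.72,Phoenix,,
22,Thomson,30,0.5,57,19,,171,Phoenix,,
22,Thomson,30,0.58,60,20,,180,Phoenix,,
23,Viani,149,0.946,69,23,,207,Phoenix,,
24,Yeoh,108,0.574,55,20,,151.25,ASTRO,,
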