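study,author,n,brfs_5y,total_dose,n_fractions,dose_per_fraction,c,definition,risk_group,subset_of_pooled
1,Aizer,352,0.748,75.6,42,,136.08,Phoenix,,
2,Arcangeli,85,0.79,80,40,,160,Phoenix,,
3,Catton,598,0.85,78,39,,156,Phoenix,,
4,Dearnaley,1065,0.883,74,37,,148,Phoenix,,
5,Eade,43,0.76,69,,2.1,144.9,Phoenix,,
5,Eade,552,0.81,72.5,,2.1,152.25,Phoenix,,
5,Eade,568,0.83,77.5,,2.1,162.75,Phoenix,,
5,Eade,367,0.89,81,,2.1,170.1,Phoenix,,
6,Incrocci,397,0.771,78,39,,156,Phoenix,,
7,Kim,56,0.641,70.2,39,,126.36,Phoenix,,
8,Kuban,150,0.78,70,35,,140,Phoenix,,
8,Kuban,151,0.85,78,39,,156,Phoenix,,
9,Kupelian,310,0.78,78,39,,156,ASTRO,,
10,Leborgne,160,0.887,78,39,,156,Phoenix,,
11,Lukka,470,0.4705,66,33,,132,ASTRO,,
12,Pollack,152,0.852,76,38,,152,Phoenix,,
13,Valdagni,161,0.7,74,37,,148,ASTRO,,
14,Yeoh,109,0.555,64,32,,128,ASTRO,,
15,Zelefsky,358,0.61,70.2,39,,126.36,Phoenix,,
15,Zelefsky,471,0.74,75.6,42,,136.08,Phoenix,,
15,Zelefsky,741,0.85,81,45,,145.8,Phoenix,,
15,Zelefsky,477,0.82,86.4,48,,155.52,Phoenix,,
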