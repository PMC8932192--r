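study,author,n,brfs_5y,total_dose,n_fractions,dose_per_fraction,c,definition,risk_group,subset_of_pooled
1,Bolzicco,100,0.944,35,5,,245,Phoenix,,
2,Kang,44,0.936,34,4,,289,Phoenix,,
3,King,1100,0.93,36.25,5,,262.8,Phoenix,,
3,King,385,0.925,35,5,,245,Phoenix,low,true
3,King,589,0.907,36.25,5,,262.8,Phoenix,intermediate,true
3,King,126,0.958,39,5,,304.2,Phoenix,high,true
4,Lee,45,0.897,36,5,,259.2,Phoenix,,
5,Loblaw,84,0.98,35,5,,245,Phoenix,,
6,Mantz,102,1,40,5,,320,Phoenix,,
7,Meier,309,0.971,40,5,,320,Phoenix,,
8,Tsang,43,0.92,36.25,5,,262.8,Phoenix,,
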