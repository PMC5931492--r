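cave,region,min_sd,max_sd,mean_sd,total_s,beta_sor,pct_turnover
Crna jama,Dinaric,2,6,3.6,8,0.66,81
Dimnice,Dinaric,1,7,3.2,8,0.76,66
Pivka jama,Dinaric,2,6,3.2,8,0.57,62
Postojnska jama,Dinaric,0,2,0.5,4,0.87,96
Skocjanske jame,Dinaric,1,5,3,8,0.73,84
Velika pasica,Dinaric,4,6,4,7,0.32,42
Zguba jama,Dinaric,0,4,1.4,6,0.59,74
Zupanova jama,Dinaric,1,10,5,13,0.77,38
Jama pod Babjim zobom,Alpine,0,3,1.6,3,0.44,0
Poloska jama,Alpine,1,3,1.8,3,0.45,0
Snezna jama,Alpine,0,2,0.8,2,0,
Zadlaska jama,Isolated,0,2,0.8,3,0.75,89
Huda luknja,Isolated,0,2,0.33,2,0.54,74
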