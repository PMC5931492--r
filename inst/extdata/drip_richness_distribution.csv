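cave,region,n_species,n_drips
Crna jama,Dinaric,2,2
Crna jama,Dinaric,3,1
Crna jama,Dinaric,5,1
Crna jama,Dinaric,6,1
Dimnice,Dinaric,1,2
Dimnice,Dinaric,2,1
Dimnice,Dinaric,5,1
Dimnice,Dinaric,7,1
Huda luknja,Isolated,0,9
Huda luknja,Isolated,1,2
Huda luknja,Isolated,2,1
Jama pod Babjim zobom,Alpine,0,1
Jama pod Babjim zobom,Alpine,1,2
Jama pod Babjim zobom,Alpine,3,2
Pivka jama,Dinaric,2,1
Pivka jama,Dinaric,4,3
Pivka jama,Dinaric,6,1
Poloska jama,Alpine,1,2
Poloska jama,Alpine,2,2
Poloska jama,Alpine,3,1
Postojnska jama,Dinaric,0,6
Postojnska jama,Dinaric,1,3
Postojnska jama,Dinaric,2,1
Snezna jama,Alpine,0,2
Snezna jama,Alpine,2,3
Skocjanske jame,Dinaric,1,1
Skocjanske jame,Dinaric,3,3
Skocjanske jame,Dinaric,5,1
Velika pasica,Dinaric,4,2
Velika pasica,Dinaric,6,2
Zadlaska jama,Isolated,0,2
Zadlaska jama,Isolated,1,2
Zadlaska jama,Isolated,2,1
Zguba jama,Dinaric,0,5
Zguba jama,Dinaric,1,1
Zguba jama,Dinaric,2,1
Zguba jama,Dinaric,3,1
Zguba jama,Dinaric,4,2
Zupanova jama,Dinaric,1,1
Zupanova jama,Dinaric,4,1
Zupanova jama,Dinaric,5,2
Zupanova jama,Dinaric,10,1
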