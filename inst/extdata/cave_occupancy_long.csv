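species,sample,site,region,count
Diacyclops languidoides,Zupanova jama,Zupanova jama,Dinaric,1
Speocyclops infernus,Crna jama,Crna jama,Dinaric,3
Speocyclops infernus,Dimnice,Dimnice,Dinaric,1
Speocyclops infernus,Jama pod Babjim zobom,Jama pod Babjim zobom,Alpine,2
Speocyclops infernus,Pivka jama,Pivka jama,Dinaric,4
Speocyclops infernus,Poloska jama,Poloska jama,Alpine,2
Speocyclops infernus,Postojnska jama,Postojnska jama,Dinaric,2
Speocyclops infernus,Snezna jama,Snezna jama,Alpine,3
Speocyclops infernus,Skocjanske jame,Skocjanske jame,Dinaric,3
Speocyclops infernus,Velika pasica,Velika pasica,Dinaric,4
Speocyclops infernus,Zadlaska jama,Zadlaska jama,Isolated,2
Speocyclops infernus,Zguba jama,Zguba jama,Dinaric,1
Speocyclops infernus,Zupanova jama,Zupanova jama,Dinaric,3
Bryocamptus balcanicus,Crna jama,Crna jama,Dinaric,2
Bryocamptus balcanicus,Huda luknja,Huda luknja,Isolated,2
Bryocamptus balcanicus,Pivka jama,Pivka jama,Dinaric,1
Bryocamptus balcanicus,Postojnska jama,Postojnska jama,Dinaric,1
Bryocamptus balcanicus,Zguba jama,Zguba jama,Dinaric,4
Bryocamptus balcanicus,Zupanova jama,Zupanova jama,Dinaric,3
Bryocamptus pyrenaicus,Velika pasica,Velika pasica,Dinaric,3
Bryocamptus pyrenaicus,Zupanova jama,Zupanova jama,Dinaric,2
Bryocamptus typhlops,Velika pasica,Velika pasica,Dinaric,4
Bryocamptus n.sp. 1,Pivka jama,Pivka jama,Dinaric,1
Bryocamptus n.sp. 2,Poloska jama,Poloska jama,Alpine,3
Bryocamptus n.sp. 2,Snezna jama,Snezna jama,Alpine,3
Bryocamptus n.sp. 2,Zadlaska jama,Zadlaska jama,Isolated,1
Elaphoidella cvetkae,Crna jama,Crna jama,Dinaric,2
Elaphoidella cvetkae,Pivka jama,Pivka jama,Dinaric,4
Elaphoidella cvetkae,Skocjanske jame,Skocjanske jame,Dinaric,1
Elaphoidella cvetkae,Zguba jama,Zguba jama,Dinaric,2
Elaphoidella cvetkae,Zupanova jama,Zupanova jama,Dinaric,3
Elaphoidella kieferi,Skocjanske jame,Skocjanske jame,Dinaric,2
Elaphoidella stammeri,Zupanova jama,Zupanova jama,Dinaric,2
Elaphoidella millennii,Velika pasica,Velika pasica,Dinaric,3
Elaphoidella millennii,Zupanova jama,Zupanova jama,Dinaric,1
Elaphoidella tarmani,Velika pasica,Velika pasica,Dinaric,1
Elaphoidella n.sp. 1,Pivka jama,Pivka jama,Dinaric,2
Elaphoidella n.sp. 2,Jama pod Babjim zobom,Jama pod Babjim zobom,Alpine,3
Elaphoidella n.sp. 3,Jama pod Babjim zobom,Jama pod Babjim zobom,Alpine,1
Lessinocamptus n.sp.,Poloska jama,Poloska jama,Alpine,5
Marenobiotus cf. brucei,Pivka jama,Pivka jama,Dinaric,2
Moraria alpina,Zadlaska jama,Zadlaska jama,Isolated,1
Moraria stankovitchi,Zupanova jama,Zupanova jama,Dinaric,1
Moraria n.sp. 1,Crna jama,Crna jama,Dinaric,1
Moraria n.sp. 1,Skocjanske jame,Skocjanske jame,Dinaric,1
Moraria n.sp. 2,Zupanova jama,Zupanova jama,Dinaric,1
Morariopsis dumonti,Velika pasica,Velika pasica,Dinaric,4
Morariopsis dumonti,Zupanova jama,Zupanova jama,Dinaric,1
Morariopsis scotenophila,Dimnice,Dimnice,Dinaric,1
Morariopsis scotenophila,Zguba jama,Zguba jama,Dinaric,2
Nitocrella n.sp.,Dimnice,Dimnice,Dinaric,2
Nitocrella n.sp.,Postojnska jama,Postojnska jama,Dinaric,1
Parastenocaris cf. andreji,Dimnice,Dimnice,Dinaric,1
Parastenocaris nolli alpina,Crna jama,Crna jama,Dinaric,1
Parastenocaris nolli alpina,Dimnice,Dimnice,Dinaric,2
Parastenocaris nolli alpina,Huda luknja,Huda luknja,Isolated,3
Parastenocaris nolli alpina,Pivka jama,Pivka jama,Dinaric,4
Parastenocaris nolli alpina,Skocjanske jame,Skocjanske jame,Dinaric,4
Parastenocaris nolli alpina,Velika pasica,Velika pasica,Dinaric,1
Parastenocaris nolli alpina,Zguba jama,Zguba jama,Dinaric,3
Parastenocaris nolli alpina,Zupanova jama,Zupanova jama,Dinaric,5
Parastenocaris n.sp. 1,Crna jama,Crna jama,Dinaric,1
Parastenocaris n.sp. 1,Dimnice,Dimnice,Dinaric,2
Parastenocaris n.sp. 2,Crna jama,Crna jama,Dinaric,3
Parastenocaris n.sp. 2,Dimnice,Dimnice,Dinaric,2
Parastenocaris n.sp. 2,Pivka jama,Pivka jama,Dinaric,4
Parastenocaris n.sp. 2,Postojnska jama,Postojnska jama,Dinaric,1
Parastenocaris n.sp. 2,Skocjanske jame,Skocjanske jame,Dinaric,3
Parastenocaris n.sp. 2,Zguba jama,Zguba jama,Dinaric,3
Parastenocaris n.sp. 2,Zupanova jama,Zupanova jama,Dinaric,1
Parastenocaris n.sp. 3,Skocjanske jame,Skocjanske jame,Dinaric,1
Parastenocaris n.sp. 3,Zupanova jama,Zupanova jama,Dinaric,1
Stygepactophanes n.sp.,Crna jama,Crna jama,Dinaric,2
Stygepactophanes n.sp.,Dimnice,Dimnice,Dinaric,3
Stygepactophanes n.sp.,Skocjanske jame,Skocjanske jame,Dinaric,1
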