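species,sample,site,region,count
,S1,Snezna jama,Alpine,0
,S2,Snezna jama,Alpine,0
Speocyclops infernus,S3,Snezna jama,Alpine,1
Speocyclops infernus,S4,Snezna jama,Alpine,1
Speocyclops infernus,S5,Snezna jama,Alpine,1
Bryocamptus n.sp. 2,S3,Snezna jama,Alpine,1
Bryocamptus n.sp. 2,S4,Snezna jama,Alpine,1
Bryocamptus n.sp. 2,S5,Snezna jama,Alpine,1
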