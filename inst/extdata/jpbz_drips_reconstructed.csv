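species,sample,site,region,count
,B1,Jama pod Babjim zobom,Alpine,0
Speocyclops infernus,B2,Jama pod Babjim zobom,Alpine,1
Speocyclops infernus,B3,Jama pod Babjim zobom,Alpine,1
Speocyclops infernus,B4,Jama pod Babjim zobom,Alpine,1
Speocyclops infernus,B5,Jama pod Babjim zobom,Alpine,1
Elaphoidella n.sp. 2,B4,Jama pod Babjim zobom,Alpine,1
Elaphoidella n.sp. 2,B5,Jama pod Babjim zobom,Alpine,1
Elaphoidella n.sp. 3,B4,Jama pod Babjim zobom,Alpine,1
Elaphoidella n.sp. 3,B5,Jama pod Babjim zobom,Alpine,1
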