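lobe,hemisphere,label,name
frontal,left,1003,caudal middle frontal
frontal,left,1012,lateral orbitofrontal
frontal,left,1014,medial orbitofrontal
frontal,left,1017,paracentral
frontal,left,1018,pars opercularis
frontal,left,1019,pars orbitalis
frontal,left,1020,pars triangularis
frontal,left,1024,precentral
frontal,left,1027,rostral middle frontal
frontal,left,1028,superior frontal
frontal,left,1032,frontal pole
temporal,left,1001,bankssts
temporal,left,1006,entorhinal
temporal,left,1007,fusiform
temporal,left,1009,inferior temporal
temporal,left,1015,middle temporal
temporal,left,1016,parahippocampal
temporal,left,1030,superior temporal
temporal,left,1033,temporal pole
temporal,left,1034,transverse temporal
parietal,left,1008,inferior parietal
parietal,left,1022,postcentral
parietal,left,1025,precuneus
parietal,left,1029,superior parietal
parietal,left,1031,supramarginal
occipital,left,1005,cuneus
occipital,left,1011,lateral occipital
occipital,left,1013,lingual
occipital,left,1021,pericalcarine
frontal,right,2003,caudal middle frontal
frontal,right,2012,lateral orbitofrontal
frontal,right,2014,medial orbitofrontal
frontal,right,2017,paracentral
frontal,right,2018,pars opercularis
frontal,right,2019,pars orbitalis
frontal,right,2020,pars triangularis
frontal,right,2024,precentral
frontal,right,2027,rostral middle frontal
frontal,right,2028,superior frontal
frontal,right,2032,frontal pole
temporal,right,2001,bankssts
temporal,right,2006,entorhinal
temporal,right,2007,fusiform
temporal,right,2009,inferior temporal
temporal,right,2015,middle temporal
temporal,right,2016,parahippocampal
temporal,right,2030,superior temporal
temporal,right,2033,temporal pole
temporal,right,2034,transverse temporal
parietal,right,2008,inferior parietal
parietal,right,2022,postcentral
parietal,right,2025,precuneus
parietal,right,2029,superior parietal
parietal,right,2031,supramarginal
occipital,right,2005,cuneus
occipital,right,2011,lateral occipital
occipital,right,2013,lingual
occipital,right,2021,pericalcarine
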