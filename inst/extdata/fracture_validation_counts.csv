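stratum,group,n_vertebrae,tp,fp,tn,fn
entire_cohort,cohort,1000,224,24,738,14
L1,level,200,89,5,103,3
L2,level,200,49,12,136,3
L3,level,200,35,2,161,2
L4,level,200,29,3,165,3
L5,level,200,22,2,173,3
in_house,institution,495,112,13,365,5
outside,institution,505,112,11,373,9
siemens,vendor,500,113,13,369,5
ge,vendor,220,50,7,162,1
philips,vendor,280,61,4,207,8
field_1.5T,field_strength,530,119,9,393,9
field_3.0T,field_strength,470,105,15,345,5
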