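"trial_id","intervention","n","mean","sd","events","mean_age","sd_age","females","fracture_parts","registered","outcome_discrepancy","rob","outcome"
"t1","HA",22,64,15,,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","CS"
"t1","NOP",23,62.5,14,,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","CS"
"t2","HA",30,61,16,,79,,55,"3-4-part",TRUE,TRUE,"moderate","CS"
"t2","NOP",30,63,15,,79,,55,"3-4-part",TRUE,TRUE,"moderate","CS"
"cai","LCP",16,66,,,71.64,,27,"3-4-part",FALSE,FALSE,"high","CS"
"cai","HA",16,60,,,71.64,,27,"3-4-part",FALSE,FALSE,"high","CS"
"o1","LCP",25,64.5,13.5,,71.8,,43,"3-4-part",FALSE,FALSE,"moderate","CS"
"o1","NOP",25,61,14,,71.8,,43,"3-4-part",FALSE,FALSE,"moderate","CS"
"o2","LCP",24,62,15,,74,,41,"3-4-part",TRUE,TRUE,"high","CS"
"o2","NOP",25,60,16,,74,,41,"3-4-part",TRUE,TRUE,"high","CS"
"o3","LCP",25,65,14,,74.59,,43,"3-4-part",FALSE,FALSE,"high","CS"
"o3","NOP",25,63.5,13,,74.59,,43,"3-4-part",FALSE,FALSE,"high","CS"
"rsaha","RSA",30,68,13,,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","CS"
"rsaha","HA",31,62,14,,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","CS"
"t1","HA",22,,,3,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","additional_surgery"
"t1","NOP",23,,,2,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","additional_surgery"
"t2","HA",30,,,4,79,,55,"3-4-part",TRUE,TRUE,"moderate","additional_surgery"
"t2","NOP",30,,,3,79,,55,"3-4-part",TRUE,TRUE,"moderate","additional_surgery"
"cai","LCP",16,,,4,71.64,,27,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"cai","HA",16,,,2,71.64,,27,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"o1","LCP",25,,,5,71.8,,43,"3-4-part",FALSE,FALSE,"moderate","additional_surgery"
"o1","NOP",25,,,2,71.8,,43,"3-4-part",FALSE,FALSE,"moderate","additional_surgery"
"o2","LCP",24,,,4,74,,41,"3-4-part",TRUE,TRUE,"high","additional_surgery"
"o2","NOP",25,,,2,74,,41,"3-4-part",TRUE,TRUE,"high","additional_surgery"
"rsaha","RSA",30,,,2,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","additional_surgery"
"rsaha","HA",31,,,4,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","additional_surgery"
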