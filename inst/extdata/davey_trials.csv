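"trial_id","intervention","n","mean","sd","events","mean_age","sd_age","females","fracture_parts","registered","outcome_discrepancy","rob","outcome"
"t1","HA",22,64,15,,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","CS"
"t1","NOP",23,62.5,14,,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","CS"
"t2","HA",30,61,16,,79,,55,"3-4-part",TRUE,TRUE,"moderate","CS"
"t2","NOP",30,63,15,,79,,55,"3-4-part",TRUE,TRUE,"moderate","CS"
"cai","LCP",16,66,,,71.64,,27,"3-4-part",FALSE,FALSE,"high","CS"
"cai","HA",16,60,,,71.64,,27,"3-4-part",FALSE,FALSE,"high","CS"
"imn1","LCP",31,62,14,,63,,45,"3-4-part",FALSE,FALSE,"high","CS"
"imn1","IMN",31,58.5,15,,63,,45,"3-4-part",FALSE,FALSE,"high","CS"
"imn2","LCP",31,60.5,15,,66,,45,"3-4-part",TRUE,TRUE,"moderate","CS"
"imn2","IMN",31,59,14.5,,66,,45,"3-4-part",TRUE,TRUE,"moderate","CS"
"imn3","LCP",30,63,14,,66.156,,43,"3-4-part",FALSE,FALSE,"high","CS"
"imn3","IMN",30,60,15.5,,66.156,,43,"3-4-part",FALSE,FALSE,"high","CS"
"lau","LCP",44,64,13.5,,73.8,,78,"2-part",TRUE,FALSE,"moderate","CS"
"lau","NOP",45,62,14.5,,73.8,,78,"2-part",TRUE,FALSE,"moderate","CS"
"ln2","LCP",25,61.5,15,,71.5,,44,"3-4-part",FALSE,FALSE,"high","CS"
"ln2","NOP",25,60,14,,71.5,,44,"3-4-part",FALSE,FALSE,"high","CS"
"ln3","LCP",29,62.5,14.5,,73.031,,50,"3-4-part",FALSE,FALSE,"moderate","CS"
"ln3","NOP",29,61,15,,73.031,,50,"3-4-part",FALSE,FALSE,"moderate","CS"
"lcprsa","LCP",62,61,15.5,,75.19,6.4,112,"3-4-part",TRUE,TRUE,"moderate","CS"
"lcprsa","RSA",62,67,13,,75.19,6.4,112,"3-4-part",TRUE,TRUE,"moderate","CS"
"rsaha","RSA",30,68,13,,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","CS"
"rsaha","HA",31,62,14,,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","CS"
"rsanop","RSA",29,66.5,12.5,,83.54,5.1,51,"3-4-part",FALSE,FALSE,"moderate","CS"
"rsanop","NOP",30,61.5,13.5,,83.54,5.1,51,"3-4-part",FALSE,FALSE,"moderate","CS"
"t1","HA",22,32,18,,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","DASH"
"t1","NOP",23,34,17,,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","DASH"
"t2","HA",30,35,19,,79,,55,"3-4-part",TRUE,TRUE,"moderate","DASH"
"t2","NOP",30,33,18,,79,,55,"3-4-part",TRUE,TRUE,"moderate","DASH"
"imn1","LCP",31,36,17,,63,,45,"3-4-part",FALSE,FALSE,"high","DASH"
"imn1","IMN",31,40,18,,63,,45,"3-4-part",FALSE,FALSE,"high","DASH"
"lau","LCP",44,30,16,,73.8,,78,"2-part",TRUE,FALSE,"moderate","DASH"
"lau","NOP",45,32,17,,73.8,,78,"2-part",TRUE,FALSE,"moderate","DASH"
"lcprsa","LCP",62,38,18,,75.19,6.4,112,"3-4-part",TRUE,TRUE,"moderate","DASH"
"lcprsa","RSA",62,31,16,,75.19,6.4,112,"3-4-part",TRUE,TRUE,"moderate","DASH"
"rsaha","RSA",30,29,15,,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","DASH"
"rsaha","HA",31,33,17,,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","DASH"
"rsanop","RSA",29,30,16,,83.54,5.1,51,"3-4-part",FALSE,FALSE,"moderate","DASH"
"rsanop","NOP",30,35,18,,83.54,5.1,51,"3-4-part",FALSE,FALSE,"moderate","DASH"
"t1","HA",22,,,3,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","additional_surgery"
"t1","NOP",23,,,2,75.15,,40,"3-4-part",FALSE,FALSE,"moderate","additional_surgery"
"t2","HA",30,,,4,79,,55,"3-4-part",TRUE,TRUE,"moderate","additional_surgery"
"t2","NOP",30,,,3,79,,55,"3-4-part",TRUE,TRUE,"moderate","additional_surgery"
"cai","LCP",16,,,4,71.64,,27,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"cai","HA",16,,,2,71.64,,27,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"imn1","LCP",31,,,5,63,,45,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"imn1","IMN",31,,,4,63,,45,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"imn2","LCP",31,,,4,66,,45,"3-4-part",TRUE,TRUE,"moderate","additional_surgery"
"imn2","IMN",31,,,5,66,,45,"3-4-part",TRUE,TRUE,"moderate","additional_surgery"
"imn3","LCP",30,,,5,66.156,,43,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"imn3","IMN",30,,,3,66.156,,43,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"lau","LCP",44,,,5,73.8,,78,"2-part",TRUE,FALSE,"moderate","additional_surgery"
"lau","NOP",45,,,3,73.8,,78,"2-part",TRUE,FALSE,"moderate","additional_surgery"
"ln2","LCP",25,,,4,71.5,,44,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"ln2","NOP",25,,,2,71.5,,44,"3-4-part",FALSE,FALSE,"high","additional_surgery"
"lcprsa","LCP",62,,,9,75.19,6.4,112,"3-4-part",TRUE,TRUE,"moderate","additional_surgery"
"lcprsa","RSA",62,,,4,75.19,6.4,112,"3-4-part",TRUE,TRUE,"moderate","additional_surgery"
"rsaha","RSA",30,,,2,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","additional_surgery"
"rsaha","HA",31,,,4,73.98,,52,"3-4-part",TRUE,FALSE,"moderate","additional_surgery"
"rsanop","RSA",29,,,2,83.54,5.1,51,"3-4-part",FALSE,FALSE,"moderate","additional_surgery"
"rsanop","NOP",30,,,3,83.54,5.1,51,"3-4-part",FALSE,FALSE,"moderate","additional_surgery"
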