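case_set,tool,rater_id,unlikely,possible,probable,definite
adric_original,naranjo,RG,0,18,22,0
adric_original,naranjo,JM,0,17,22,1
adric_original,naranjo,KB,0,18,21,1
adric_original,naranjo,MT,0,14,24,2
adric_original,naranjo,TN,0,10,29,1
adric_original,naranjo,MP,0,12,27,1
adric_original,naranjo,RS,0,11,27,2
adric_original,liverpool,RG,0,7,23,10
adric_original,liverpool,JM,0,15,8,17
adric_original,liverpool,KB,0,18,4,18
adric_original,liverpool,MT,1,5,17,17
adric_original,liverpool,TN,0,3,15,22
adric_original,liverpool,MP,0,7,12,21
adric_original,liverpool,RS,0,7,13,20
annals,liverpool,RG,0,11,18,8
annals,liverpool,JM,0,11,20,6
annals,liverpool,KB,0,12,19,6
annals,liverpool,MT,0,10,18,9
annals,liverpool,TN,1,10,20,6
annals,liverpool,MP,0,10,17,10
annals,liverpool,RS,0,3,24,10
adric_new,naranjo,RG,0,18,21,1
adric_new,naranjo,JM,0,19,21,0
adric_new,naranjo,KB,0,15,25,0
adric_new,naranjo,MT,1,9,27,3
adric_new,naranjo,TN,0,13,27,0
adric_new,naranjo,MP,0,12,28,0
adric_new,naranjo,RS,0,4,36,0
adric_new,liverpool,RG,0,11,12,17
adric_new,liverpool,JM,0,14,8,18
adric_new,liverpool,KB,0,13,10,17
adric_new,liverpool,MT,0,8,9,23
adric_new,liverpool,TN,0,8,12,20
adric_new,liverpool,MP,0,9,13,18
adric_new,liverpool,RS,0,3,17,20
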