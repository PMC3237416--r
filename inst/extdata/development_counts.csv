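set,n_cases,n_raters,unlikely,possible,probable,definite
iteration1_adric,20,7,1,18,2,119
iteration2_adric,10,7,0,24,39,7
iteration2_adult,10,7,0,13,48,9
annals_author_naranjo,37,1,0,5,29,3
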