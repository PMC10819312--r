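material,energy_mev,stopping_mev_cm2_g
Ti,10,30.418126
Ti,15,22.237424
Ti,20,17.766552
Ti,25,14.918791
Ti,30,12.934028
Ti,40,10.332671
Ti,50,8.692456
Ti,60,7.558085
Ti,70,6.724225
Al,10,34.278735
Al,15,24.918388
Al,20,19.839325
Al,25,16.618680
Al,30,14.381172
Al,40,11.458088
Al,50,9.621027
Al,60,8.353470
Al,70,7.423355
Ni,10,29.556686
Ni,15,21.726868
Ni,20,17.416978
Ni,25,14.659522
Ni,30,12.731680
Ni,40,10.196881
Ni,50,8.593566
Ni,60,7.482225
Ni,70,6.663905
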