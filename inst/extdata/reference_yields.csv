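scenario,e_entry_mev,t_irr_h,nuclide,activity_mbq
E<25,25,24,Sc-47,73
E<25,25,24,Sc-44g,447
E<25,25,24,Sc-44m,39
E<30,30,24,Sc-47,198
E<30,30,24,Sc-44g,1792
E<30,30,24,Sc-44m,154
E<35,35,24,Sc-47,364
E<35,35,24,Sc-46,4.8
E<35,35,24,Sc-44g,3270
E<35,35,24,Sc-44m,297
E<35,35,24,Sc-43,19.9
E<40,40,24,Sc-47,556
E<40,40,24,Sc-46,19.4
E<40,40,24,Sc-44g,4232
E<40,40,24,Sc-44m,412
E<40,40,24,Sc-43,289
E<25,25,80,Sc-47,196
E<25,25,80,Sc-44g,454
E<25,25,80,Sc-44m,96
E<30,30,80,Sc-47,529
E<30,30,80,Sc-44g,1820
E<30,30,80,Sc-44m,381
E<35,35,80,Sc-47,971
E<35,35,80,Sc-46,15.8
E<35,35,80,Sc-44g,3320
E<35,35,80,Sc-44m,736
E<35,35,80,Sc-43,20.2
E<40,40,80,Sc-47,1481
E<40,40,80,Sc-46,64
E<40,40,80,Sc-44g,4298
E<40,40,80,Sc-44m,1019
E<40,40,80,Sc-43,293
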