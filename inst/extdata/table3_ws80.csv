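position,species,size_class,mass_Mg_ha
downed,2,1,0
downed,2,2,3.90
downed,2,3,11.21
downed,2,4,20.90
downed,2,5,23.80
downed,2,6,10.20
downed,1,1,0
downed,1,2,7.30
downed,1,3,11.98
downed,1,4,17.19
downed,1,5,12.00
downed,1,6,0
standing,2,1,0
standing,2,2,0
standing,2,3,0.50
standing,2,4,2.49
standing,2,5,3.49
standing,2,6,1.50
standing,1,1,0
standing,1,2,0.50
standing,1,3,1.01
standing,1,4,1.02
standing,1,5,1.01
standing,1,6,0
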