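species,records
crab-eating fox,1176
brown-nosed coati,419
crab-eating raccoon,77
ocelot,68
other carnivores,33
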