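species_a	species_b
Genus09 sp01	Genus09 sp02
Genus07 sp01	Genus07 sp02
Genus10 sp01	Genus10 sp02
Genus03 sp01	Genus03 sp02
Genus02 sp01	Genus02 sp02
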