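specimen_id	species	genus	family
Genus01_sp01_01	Genus01 sp01	Genus01	Family01
Genus01_sp01_02	Genus01 sp01	Genus01	Family01
Genus01_sp01_03	Genus01 sp01	Genus01	Family01
Genus01_sp02_01	Genus01 sp02	Genus01	Family01
Genus01_sp02_02	Genus01 sp02	Genus01	Family01
Genus01_sp02_03	Genus01 sp02	Genus01	Family01
Genus02_sp01_01	Genus02 sp01	Genus02	Family02
Genus02_sp01_02	Genus02 sp01	Genus02	Family02
Genus02_sp01_03	Genus02 sp01	Genus02	Family02
Genus02_sp02_01	Genus02 sp02	Genus02	Family02
Genus02_sp02_02	Genus02 sp02	Genus02	Family02
Genus02_sp02_03	Genus02 sp02	Genus02	Family02
Genus03_sp01_01	Genus03 sp01	Genus03	Family03
Genus03_sp01_02	Genus03 sp01	Genus03	Family03
Genus03_sp01_03	Genus03 sp01	Genus03	Family03
Genus03_sp02_01	Genus03 sp02	Genus03	Family03
Genus03_sp02_02	Genus03 sp02	Genus03	Family03
Genus03_sp02_03	Genus03 sp02	Genus03	Family03
Genus04_sp01_01	Genus04 sp01	Genus04	Family04
Genus04_sp01_02	Genus04 sp01	Genus04	Family04
Genus04_sp01_03	Genus04 sp01	Genus04	Family04
Genus04_sp02_01	Genus04 sp02	Genus04	Family04
Genus04_sp02_02	Genus04 sp02	Genus04	Family04
Genus04_sp02_03	Genus04 sp02	Genus04	Family04
Genus05_sp01_01	Genus05 sp01	Genus05	Family05
Genus05_sp01_02	Genus05 sp01	Genus05	Family05
Genus05_sp01_03	Genus05 sp01	Genus05	Family05
Genus05_sp02_01	Genus05 sp02	Genus05	Family05
Genus05_sp02_02	Genus05 sp02	Genus05	Family05
Genus05_sp02_03	Genus05 sp02	Genus05	Family05
Genus06_sp01_01	Genus06 sp01	Genus06	Family06
Genus06_sp01_02	Genus06 sp01	Genus06	Family06
Genus06_sp01_03	Genus06 sp01	Genus06	Family06
Genus06_sp02_01	Genus06 sp02	Genus06	Family06
Genus06_sp02_02	Genus06 sp02	Genus06	Family06
Genus06_sp02_03	Genus06 sp02	Genus06	Family06
Genus07_sp01_01	Genus07 sp01	Genus07	Family07
Genus07_sp01_02	Genus07 sp01	Genus07	Family07
Genus07_sp01_03	Genus07 sp01	Genus07	Family07
Genus07_sp02_01	Genus07 sp02	Genus07	Family07
Genus07_sp02_02	Genus07 sp02	Genus07	Family07
Genus07_sp02_03	Genus07 sp02	Genus07	Family07
Genus08_sp01_01	Genus08 sp01	Genus08	Family08
Genus08_sp01_02	Genus08 sp01	Genus08	Family08
Genus08_sp01_03	Genus08 sp01	Genus08	Family08
Genus08_sp02_01	Genus08 sp02	Genus08	Family08
Genus08_sp02_02	Genus08 sp02	Genus08	Family08
Genus08_sp02_03	Genus08 sp02	Genus08	Family08
Genus09_sp01_01	Genus09 sp01	Genus09	Family09
Genus09_sp01_02	Genus09 sp01	Genus09	Family09
Genus09_sp01_03	Genus09 sp01	Genus09	Family09
Genus09_sp02_01	Genus09 sp02	Genus09	Family09
Genus09_sp02_02	Genus09 sp02	Genus09	Family09
Genus09_sp02_03	Genus09 sp02	Genus09	Family09
Genus10_sp01_01	Genus10 sp01	Genus10	Family10
Genus10_sp01_02	Genus10 sp01	Genus10	Family10
Genus10_sp01_03	Genus10 sp01	Genus10	Family10
Genus10_sp02_01	Genus10 sp02	Genus10	Family10
Genus10_sp02_02	Genus10 sp02	Genus10	Family10
Genus10_sp02_03	Genus10 sp02	Genus10	Family10
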