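host_family,clade
Amaranthaceae,eudicot
Apiaceae,eudicot
Apocynaceae,eudicot
Asteraceae,eudicot
Betulaceae,eudicot
Boraginaceae,eudicot
Brassicaceae,eudicot
Cactaceae,eudicot
Caryophyllaceae,eudicot
Cistaceae,eudicot
Cupressaceae,gymnosperm
Cyperaceae,monocot
Dipterocarpaceae,eudicot
Ericaceae,eudicot
Euphorbiaceae,eudicot
Fabaceae,eudicot
Fagaceae,eudicot
Lamiaceae,eudicot
Lauraceae,other_angiosperm
Magnoliaceae,other_angiosperm
Malvaceae,eudicot
Moraceae,eudicot
Myrtaceae,eudicot
Oleaceae,eudicot
Orchidaceae,monocot
Pinaceae,gymnosperm
Plantaginaceae,eudicot
Poaceae,monocot
Polygonaceae,eudicot
Ranunculaceae,eudicot
Rosaceae,eudicot
Rubiaceae,eudicot
Rutaceae,eudicot
Salicaceae,eudicot
Sapindaceae,eudicot
Solanaceae,eudicot
Vitaceae,eudicot
Zygophyllaceae,eudicot
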