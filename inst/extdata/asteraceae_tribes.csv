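host_genus,tribe
Achillea,Anthemideae
Ambrosia,Heliantheae
Anthemis,Anthemideae
Artemisia,Anthemideae
Aster,Astereae
Baccharis,Astereae
Bidens,Coreopsideae
Calendula,Calenduleae
Carduus,Cardueae
Carlina,Cardueae
Centaurea,Cardueae
Chrysanthemum,Anthemideae
Cichorium,Cichorieae
Cirsium,Cardueae
Conyza,Astereae
Cousinia,Cardueae
Echinops,Cardueae
Erigeron,Astereae
Eupatorium,Eupatorieae
Gnaphalium,Gnaphalieae
Helianthus,Heliantheae
Helichrysum,Gnaphalieae
Inula,Inuleae
Lactuca,Cichorieae
Launaea,Cichorieae
Matricaria,Anthemideae
Mutisia,Mutisieae
Olearia,Astereae
Onopordum,Cardueae
Pulicaria,Inuleae
Senecio,Senecioneae
Solidago,Astereae
Sonchus,Cichorieae
Tanacetum,Anthemideae
Taraxacum,Cichorieae
Vernonia,Vernonieae
Xanthium,Heliantheae
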