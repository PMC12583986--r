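species,feature,value
Komagataeibacter xylinus,methyl_3_product,present
Komagataeibacter xylinus,methyl_2_product,unknown
Methylocella palustris,methyl_2_product,absent
Methylocella palustris,methyl_3_product,absent
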