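order,genomes_total,genomes_with_shc,genera_total,genera_with_shc
Hyphomicrobiales,2618,791,171,46
Rhodobacterales,1337,4,203,3
Rhodospirillales,673,475,106,73
Sphingomonadales,1129,123,51,9
Other,753,16,78,7
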