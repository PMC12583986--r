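order,family,species,strain,dsm_culture,genome_assembly
Rhodospirillales,Acetobacteraceae,Muricoccus pecuniae,N75,25622,GCF_014199205.1
Rhodospirillales,Acetobacteraceae,Rhodopila globiformis,7950,161,GCF_002937115.1
Rhodospirillales,Acetobacteraceae,Acidocella aminolytica,101,11237,GCF_900129125.1
Rhodospirillales,Acetobacteraceae,Gluconacetobacter diazotrophicus,PA 5,5601,GCF_000021325.1
Rhodospirillales,Acetobacteraceae,Komagataeibacter xylinus,R-2277,NA,GCF_000964505.1
Rhodospirillales,Acetobacteraceae,Komagataeibacter europaeus,JK2,13110,GCF_002173515.1
Rhodospirillales,Acetobacteraceae,Kozakia baliensis,YO-3,14400,GCF_001787335.1
Rhodospirillales,Acetobacteraceae,Asaia siamensis,S60-1,15972,GCF_014635085.1
Rhodospirillales,Acetobacteraceae,Gluconobacter oxydans,CN 1221,2003,GCF_000507285.1
Rhodospirillales,Acetobacteraceae,Acetobacter pasteurianus,190,3509,GCF_003850805.1
Rhodospirillales,Rhodovibrionaceae,Limimonas halophila,IA16,25584,GCF_900100655.1
Rhodospirillales,Rhodovibrionaceae,Pelagibius litoralis,CL-UU02,21314,GCF_011683915.1
Rhodospirillales,Rhodovibrionaceae,Tistlia consotensis,USBA 355,21585,GCF_900188055.1
Rhodospirillales,Rhodospirillaceae,Rhodospirillum rubrum,S 1,467,GCF_019134555.1
Rhodospirillales,Rhodospirillaceae,Magnetospirillum fulvum,1360,113,GCF_900108475.1
Rhodospirillales,Reyranellaceae,Enhydrobacter aerosaccus,G,8914,GCF_900167455.1
Rhodospirillales,Rhodospirillaceae,Hypericibacter terrae,R5913,109816,GCF_008728855.1
Rhodospirillales,Azospirillaceae,Skermanella aerolata,5416 T-32,18479,GCF_000936425.1
Rhodospirillales,Azospirillaceae,Nitrospirillum amazonense,Y-1,2787,GCF_029594735.1
Rhodospirillales,Azospirillaceae,Azospirillum brasilense,Sp 7,1690,GCF_008274945.1
Sphingomonadales,Erythrobacteraceae,Novosphingobium nitrogenifigens,Y88,19370,GCF_000192575.1
Sphingomonadales,Erythrobacteraceae,Novosphingobium acidiphilum,FSW 06-204d,19966,GCF_000429005.1
Sphingomonadales,Erythrobacteraceae,Novosphingobium rosa,R13-5,7285,GCF_001598555.1
Sphingomonadales,Sphingomonadaceae,Sphingomonas mali,Y-347,10565,GCF_001598415.1
Sphingomonadales,Sphingomonadaceae,Stakelama sediminis,CJ70,27203,GCF_014199335.1
Sphingomonadales,Sphingomonadaceae,Sphingomonas alpina,S8-3,22537,GCF_014490665.1
Sphingomonadales,Sphingomonadaceae,Sphingomonas changbaiensis,V2M44,25652,GCF_000974765.1
Sphingomonadales,Sphingomonadaceae,Sphingomonas formosensis,CC-Nfb-2,24164,GCF_009755815.1
Sphingomonadales,Sphingomonadaceae,Sphingomonas haloaromaticamans,A175,13477,GCF_001853345.1
Sphingomonadales,Sphingomonadaceae,Sphingobium estronivorans,AXB,102173,GCF_008692605.1
Micropepsales,Micropepsaceae,Rhizomicrobium palustre,A48,19867,GCF_011761565.1
Hyphomicrobiales,Rhizobiaceae,Rhizobium tropici,HAMBI 1163,11418,GCF_000330885.1
Hyphomicrobiales,Rhizobiaceae,Ensifer sojae,CCBAU 05684,26426,GCF_002288525.1
Hyphomicrobiales,Stappiaceae,Roseibium album,50 M6,18320,GCF_001404515.1
Hyphomicrobiales,Stappiaceae,Roseibium marinum,mano 18,17023,GCF_002906165.1
Hyphomicrobiales,Parvibaculaceae,Rhodoligotrophos appendicifer,120-1,23582,GCF_007474605.1
Hyphomicrobiales,Hyphomicrobiaceae,Rhodomicrobium vannielii,ATH 3.1.1,162,GCF_000166055.1
Hyphomicrobiales,Hyphomicrobiaceae,Hyphomicrobium facile,H-526,1565,GCF_900116175.1
Hyphomicrobiales,Chelatococcaceae,Chelatococcus reniformis,JCM 30308,105737,GCF_014640075.1
Hyphomicrobiales,Methylobacteriaceae,Enterovirga rhinocerotis,YIM 100770,25903,GCF_004363955.1
Hyphomicrobiales,Methylobacteriaceae,Microvirga massiliensis,JC119,26813,GCF_001006805.1
Hyphomicrobiales,Methylobacteriaceae,Methylobacterium soli,YIM 48816,21955,GCF_008806385.1
Hyphomicrobiales,Methylobacteriaceae,Methylobacterium oxalidis,35a,24028,GCF_022179505.1
Hyphomicrobiales,Methylobacteriaceae,Methylorubrum rhodesianum,D2_2,103741,GCF_014199985.1
Hyphomicrobiales,Methylobacteriaceae,Methylobacterium aquaticum,GR16,16371,GCF_001043915.1
Hyphomicrobiales,Roseiarcaceae,Roseiarcus fermentans,Pf56,24875,GCF_003315135.1
Hyphomicrobiales,Beijerinckiaceae,Methyloferula stellata,AR4,22108,GCF_000385335.1
Hyphomicrobiales,Beijerinckiaceae,Methylocella palustris,K,NA,GCF_038024855.1
Hyphomicrobiales,Beijerinckiaceae,Beijerinckia indica,B.102.C,591,GCF_000019845.1
Hyphomicrobiales,Nitrobacteraceae,Rhodoplanes elegans,AS130,11907,GCF_016653355.1
Hyphomicrobiales,Nitrobacteraceae,Variibacter gotjawalensis,GJW-30,29671,GCF_004216635.1
Hyphomicrobiales,Nitrobacteraceae,Afipia broomeae,B91-007286,7327,GCF_000314675.2
Hyphomicrobiales,Nitrobacteraceae,Rhodopseudomonas parapalustris,Dr.1,130,GCF_000013365.1
Hyphomicrobiales,Nitrobacteraceae,Bradyrhizobium elkanii,USDA61,11554,GCF_012871055.1
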