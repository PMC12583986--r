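order,family,species,hop22_29_ene,hop17_21_ene,diplopterol,tetrahymanol,sum_bhpds,s22_pct,n_bhpds,pct_unsaturated,pct_pentol_hexol
Rhodospirillales,Acetobacteraceae,Muricoccus pecuniae,BD,BD,BD,BD,0.1,BD,1,0,0
Rhodospirillales,Acetobacteraceae,Rhodopila globiformis,0.12,BD,BD,BD,1.3,BD,5,0,19
Rhodospirillales,Acetobacteraceae,Acidocella aminolytica,0.11,BD,BD,BD,2.7,BD,11,3,21
Rhodospirillales,Acetobacteraceae,Gluconacetobacter diazotrophicus,BD,BD,BD,BD,27.3,79,15,49,6
Rhodospirillales,Acetobacteraceae,Komagataeibacter xylinus,NA,NA,NA,NA,NA,NA,23,71,24
Rhodospirillales,Acetobacteraceae,Komagataeibacter europaeus,BD,BD,0.12,BD,1.3,7,25,54,50
Rhodospirillales,Acetobacteraceae,Kozakia baliensis,BD,BD,0.14,BD,5.3,15,33,56,29
Rhodospirillales,Acetobacteraceae,Asaia siamensis,0.07,0.08,0.88,BD,12.9,14,18,58,15
Rhodospirillales,Acetobacteraceae,Gluconobacter oxydans,BD,BD,0.87,BD,13.3,27,19,56,18
Rhodospirillales,Acetobacteraceae,Acetobacter pasteurianus,BD,BD,1.7,BD,14.9,25,15,82,19
Rhodospirillales,Rhodovibrionaceae,Limimonas halophila,BD,BD,0.05,BD,1.4,BD,1,0,0
Rhodospirillales,Rhodovibrionaceae,Pelagibius litoralis,BD,BD,BD,BD,2.2,BD,2,0,0
Rhodospirillales,Rhodovibrionaceae,Tistlia consotensis,BD,BD,BD,BD,3.9,BD,4,0,0
Rhodospirillales,Rhodospirillaceae,Rhodospirillum rubrum,0.38,BD,BD,BD,8.1,BD,4,0,0
Rhodospirillales,Rhodospirillaceae,Magnetospirillum fulvum,BD,BD,BD,BD,0.9,BD,5,0,0
Rhodospirillales,Reyranellaceae,Enhydrobacter aerosaccus,BD,BD,BD,BD,1.4,BD,9,1,77
Rhodospirillales,Rhodospirillaceae,Hypericibacter terrae,0.27,0.04,BD,BD,3.9,BD,17,4,5
Rhodospirillales,Azospirillaceae,Skermanella aerolata,BD,BD,BD,BD,BD,BD,9,37,26
Rhodospirillales,Azospirillaceae,Nitrospirillum amazonense,0.20,BD,BD,BD,16.2,BD,11,0,44
Rhodospirillales,Azospirillaceae,Azospirillum brasilense,BD,BD,BD,BD,BD,BD,1,0,0
Sphingomonadales,Erythrobacteraceae,Novosphingobium nitrogenifigens,0.51,0.03,0.06,BD,5.5,BD,9,0,15
Sphingomonadales,Erythrobacteraceae,Novosphingobium acidiphilum,BD,BD,BD,BD,BD,BD,0,NA,NA
Sphingomonadales,Erythrobacteraceae,Novosphingobium rosa,BD,BD,BD,BD,6.5,BD,1,0,0
Sphingomonadales,Sphingomonadaceae,Sphingomonas mali,BD,BD,BD,BD,1.1,BD,2,0,90
Sphingomonadales,Sphingomonadaceae,Stakelama sediminis,2.1,0.07,BD,BD,1.0,BD,6,0,20
Sphingomonadales,Sphingomonadaceae,Sphingomonas alpina,BD,BD,BD,BD,BD,BD,0,NA,NA
Sphingomonadales,Sphingomonadaceae,Sphingomonas changbaiensis,0.34,BD,BD,BD,1.4,BD,4,0,0
Sphingomonadales,Sphingomonadaceae,Sphingomonas formosensis,BD,BD,BD,BD,0.5,BD,5,1,23
Sphingomonadales,Sphingomonadaceae,Sphingomonas haloaromaticamans,0.03,BD,BD,BD,0.6,BD,6,0,51
Sphingomonadales,Sphingomonadaceae,Sphingobium estronivorans,BD,BD,BD,BD,0.4,BD,5,0,41
Micropepsales,Micropepsaceae,Rhizomicrobium palustre,BD,BD,BD,BD,11.9,BD,2,0,1
Hyphomicrobiales,Rhizobiaceae,Rhizobium tropici,BD,BD,BD,BD,BD,BD,0,NA,NA
Hyphomicrobiales,Rhizobiaceae,Ensifer sojae,BD,BD,BD,BD,BD,BD,0,NA,NA
Hyphomicrobiales,Stappiaceae,Roseibium album,BD,BD,BD,BD,BD,BD,0,NA,NA
Hyphomicrobiales,Stappiaceae,Roseibium marinum,BD,BD,BD,BD,BD,BD,0,NA,NA
Hyphomicrobiales,Parvibaculaceae,Rhodoligotrophos appendicifer,BD,BD,2.8,BD,1.3,BD,4,0,0
Hyphomicrobiales,Hyphomicrobiaceae,Rhodomicrobium vannielii,0.48,BD,BD,BD,12.9,BD,8,0,0
Hyphomicrobiales,Hyphomicrobiaceae,Hyphomicrobium facile,BD,BD,0.02,BD,3.0,BD,4,0,0
Hyphomicrobiales,Chelatococcaceae,Chelatococcus reniformis,BD,BD,BD,BD,1.3,BD,4,0,0
Hyphomicrobiales,Methylobacteriaceae,Enterovirga rhinocerotis,0.05,0.06,0.46,BD,0.3,BD,10,1,1
Hyphomicrobiales,Methylobacteriaceae,Microvirga massiliensis,BD,BD,BD,BD,BD,BD,2,0,0
Hyphomicrobiales,Methylobacteriaceae,Methylobacterium soli,0.13,0.09,1.4,BD,3.1,BD,12,0,0
Hyphomicrobiales,Methylobacteriaceae,Methylobacterium oxalidis,0.37,0.15,1.3,BD,1.4,BD,12,0,0
Hyphomicrobiales,Methylobacteriaceae,Methylorubrum rhodesianum,BD,0.03,0.34,BD,2.4,BD,11,0,0
Hyphomicrobiales,Methylobacteriaceae,Methylobacterium aquaticum,0.08,0.02,1.6,BD,5.0,BD,9,0,0
Hyphomicrobiales,Roseiarcaceae,Roseiarcus fermentans,BD,BD,BD,BD,2.4,BD,6,0,0
Hyphomicrobiales,Beijerinckiaceae,Methyloferula stellata,BD,BD,3.8,BD,7.1,BD,15,0,0
Hyphomicrobiales,Beijerinckiaceae,Methylocella palustris,NA,NA,NA,NA,NA,BD,5,0,0
Hyphomicrobiales,Beijerinckiaceae,Beijerinckia indica,BD,BD,1.8,BD,1.5,BD,7,0,0
Hyphomicrobiales,Nitrobacteraceae,Rhodoplanes elegans,BD,BD,0.09,0.69,0.9,BD,17,0,0
Hyphomicrobiales,Nitrobacteraceae,Variibacter gotjawalensis,0.91,0.06,BD,BD,1.0,BD,5,0,0
Hyphomicrobiales,Nitrobacteraceae,Afipia broomeae,0.12,BD,0.20,BD,8.3,BD,16,43,0
Hyphomicrobiales,Nitrobacteraceae,Rhodopseudomonas parapalustris,BD,BD,1.2,1.1,2.5,BD,10,0,0
Hyphomicrobiales,Nitrobacteraceae,Bradyrhizobium elkanii,BD,BD,0.26,0.61,2.1,BD,12,0,0
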