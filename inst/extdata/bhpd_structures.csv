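structure_id,label,side_chain_class,subtype,base,stage,ring_a_methyl,unsaturation,c22_config,isomer_note,source
Ia,22R-adenosylhopane,nucleoside,adenosyl,NA,NA,none,,R,,narrated
Ia-22S,22S-adenosylhopane,nucleoside,adenosyl,NA,NA,none,,S,,narrated
Ia-uns,d6 22R-adenosylhopane,nucleoside,adenosyl,NA,NA,none,d6,R,,narrated
Ia-2Me,2-Me adenosylhopane,nucleoside,adenosyl,NA,NA,2Me,,R,,narrated
Ib-1,monomethyl-adenosylhopane isomer 1,nucleoside,Me-adenosyl,NA,NA,none,,R,isomer 1,narrated
Ib-2,monomethyl-adenosylhopane isomer 2,nucleoside,Me-adenosyl,NA,NA,none,,R,isomer 2,narrated
Ib-3,monomethyl-adenosylhopane isomer 3,nucleoside,Me-adenosyl,NA,NA,none,,R,isomer 3,narrated
Ic,dimethyl-adenosylhopane,nucleoside,diMe-adenosyl,NA,NA,none,,R,,narrated
Id,inosylhopane,nucleoside,inosyl,NA,NA,none,,R,,narrated
Ie,N-methyl-inosylhopane,nucleoside,N-Me-inosyl,NA,NA,none,,R,,narrated
IIa,BHT (22R),tetrol,NA,NA,NA,none,,R,"22R,34R/S pair",narrated
IIa-22S,BHT (22S),tetrol,NA,NA,NA,none,,S,"22S,34S",narrated
IIa-d6,d6 BHT,tetrol,NA,NA,NA,none,d6,R,,narrated
IIa-d11,d11 BHT,tetrol,NA,NA,NA,none,d11,R,,narrated
IIa-d6d11,"d6,11 BHT",tetrol,NA,NA,NA,none,d6;d11,R,,narrated
IIa-2Me,2-Me BHT,tetrol,NA,NA,NA,2Me,,R,,narrated
IIa-3Me,3-Me BHT,tetrol,NA,NA,NA,3Me,,R,,narrated
IIa-3Me-d6,3-Me d6 BHT,tetrol,NA,NA,NA,3Me,d6,R,,narrated
IIa-3Me-d6d11,"3-Me d6,11 BHT",tetrol,NA,NA,NA,3Me,d6;d11,R,,narrated
IIb,35-O-methyl BHT,tetrol_derivative,Me-ether,NA,NA,none,,R,,narrated
IIb-uns,d6 35-O-methyl BHT,tetrol_derivative,Me-ether,NA,NA,none,d6,R,,narrated
IIc,35-ethenolamine BHT,tetrol_derivative,ethenolamine,NA,NA,none,,R,,narrated
IId,monoacyl BHT,tetrol_derivative,monoacyl,NA,NA,none,,R,,narrated
IIe,diacyl BHT,tetrol_derivative,diacyl,NA,NA,none,,R,,narrated
IIf,BHpentol,pentol,NA,NA,NA,none,,R,,narrated
IIf-uns,monounsaturated BHpentol,pentol,NA,NA,NA,none,d6,R,,inferred
IIg,anhydro-BHpentol,anhydro_pentol,NA,NA,NA,none,,R,,inferred
IIg-uns,monounsaturated anhydro-BHpentol,anhydro_pentol,NA,NA,NA,none,d6,R,,narrated
IIi,BHhexol,hexol,NA,NA,NA,none,,R,,narrated
IIIa,BHT N-acetylglucosamine,ce_series,NA,tetrol,acetylglucosamine,none,,R,,narrated
IIIa-uns,monounsaturated BHT N-acetylglucosamine,ce_series,NA,tetrol,acetylglucosamine,none,d6,R,,inferred
IIIb,BHT glucosamine,ce_series,NA,tetrol,glucosamine,none,,R,,narrated
IIIb-late,BHT glucosamine late isomer,ce_series,NA,tetrol,glucosamine,none,,unknown,later eluting,narrated
IIIb-uns,monounsaturated BHT glucosamine,ce_series,NA,tetrol,glucosamine,none,d6,R,,narrated
IIIb-3Me,3-Me BHT glucosamine,ce_series,NA,tetrol,glucosamine,3Me,,R,,narrated
IIIc,BHT cyclitol ether,ce_series,NA,tetrol,cyclitol,none,,R,,narrated
IIIc-22S,BHT cyclitol ether (22S),ce_series,NA,tetrol,cyclitol,none,,S,earlier eluting,narrated
IIIc-late,BHT cyclitol ether late isomer,ce_series,NA,tetrol,cyclitol,none,,unknown,later eluting,narrated
IIIc-uns,monounsaturated BHT CE,ce_series,NA,tetrol,cyclitol,none,d6,R,,narrated
IIIc-Me,BHT CE methylated in the cyclitol,ce_series,NA,tetrol,Me-cyclitol,none,,R,,narrated
IIIc-3Me-d6,3-Me d6 BHT CE,ce_series,NA,tetrol,cyclitol,3Me,d6,R,,narrated
IIIc-3Me-d6d11,"3-Me d6,11 BHT CE",ce_series,NA,tetrol,cyclitol,3Me,d6;d11,R,,narrated
IIId,BHpentol cyclitol ether,ce_series,NA,pentol,cyclitol,none,,R,,narrated
IIId-d6,d6 BHpentol CE,ce_series,NA,pentol,cyclitol,none,d6,R,,narrated
IIId-d11,d11 BHpentol CE,ce_series,NA,pentol,cyclitol,none,d11,R,,narrated
IIId-d6d11,"d6,11 BHpentol CE",ce_series,NA,pentol,cyclitol,none,d6;d11,R,,narrated
IIId-3Me,3-Me BHpentol CE,ce_series,NA,pentol,cyclitol,3Me,,R,,narrated
IIId-3Me-uns,3-Me monounsaturated BHpentol CE,ce_series,NA,pentol,cyclitol,3Me,d6,R,,narrated
IIIe,BHhexol cyclitol ether,ce_series,NA,hexol,cyclitol,none,,R,,narrated
IIIe-uns,monounsaturated BHhexol CE,ce_series,NA,hexol,cyclitol,none,d6,R,,narrated
IVa,carbamoyl BHT,carbamoyl,NA,tetrol,NA,none,,R,,narrated
IVa-uns,monounsaturated carbamoyl BHT,carbamoyl,NA,tetrol,NA,none,d6,R,,inferred
IVb,carbamoyl BHpentol,carbamoyl,NA,pentol,NA,none,,R,,narrated
IVc,carbamoyl BHhexol,carbamoyl,NA,hexol,NA,none,,R,,narrated
Va,35-aminobacteriohopanetriol,amino,aminotriol,NA,NA,none,,R,,narrated
Va-late,35-aminotriol late isomer,amino,aminotriol,NA,NA,none,,unknown,later eluting,narrated
Va-uns,d6 35-aminotriol,amino,aminotriol,NA,NA,none,d6,R,,narrated
Va-2Me,2-Me 35-aminotriol,amino,aminotriol,NA,NA,2Me,,R,,narrated
Vb,aminotetrol,amino,aminotetrol,NA,NA,none,,R,,narrated
Vb-uns,monounsaturated aminotetrol,amino,aminotetrol,NA,NA,none,d6,R,,inferred
Vc,N-tryptophanyl 35-aminotriol,amino,N-acyl-amino-acid,NA,NA,none,,R,tryptophanyl,narrated
Vd,N-phenylalanyl 35-aminotriol,amino,N-acyl-amino-acid,NA,NA,none,,R,phenylalanyl,narrated
Ve,N-ornithinyl 35-aminotriol,amino,N-acyl-amino-acid,NA,NA,none,,R,ornithinyl,narrated
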