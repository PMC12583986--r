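{
  "catalog_version": "1.0",
  "description": "Gene-family catalog for the hopanoid/BHPD biosynthesis pathway in Alphaproteobacteria. canonical_order follows the hpnA-hpnR lettering of the canonical hpn gene cluster (shc = hpnF); genes with canonical_order null are not scored for cluster gene order. similarity_threshold is the percent-similarity acceptance cutoff for homology calls; the stricter hpnP cutoff reflects cross-reactivity with other B12-binding radical SAM proteins. shc_decoy_floor is the percent similarity below which a squalene-hopene cyclase candidate is treated as the distantly related secondary Shc clade.",
  "shc_decoy_floor": 40,
  "default_similarity_threshold": 50,
  "families": [
    {"family_id": "dxs",   "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_DXS",   "note": "1-deoxy-D-xylulose-5-phosphate synthase"},
    {"family_id": "dxr",   "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_DXR",   "note": "DXP reductoisomerase"},
    {"family_id": "ispD",  "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_ISPD",  "note": "CDP-ME synthase"},
    {"family_id": "ispE",  "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_ISPE",  "note": "CDP-ME kinase"},
    {"family_id": "ispF",  "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_ISPF",  "note": "MEcDP synthase"},
    {"family_id": "ispDF", "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_ISPDF", "note": "fused ispD-ispF gene, common in Alphaproteobacteria"},
    {"family_id": "ispG",  "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_ISPG",  "note": "HMBDP synthase"},
    {"family_id": "ispH",  "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_ISPH",  "note": "HMBDP reductase"},
    {"family_id": "ispA",  "pathway_stage": "MEP",          "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_ISPA",  "note": "farnesyl diphosphate synthase"},
    {"family_id": "aceE",  "pathway_stage": "accessory",    "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_ACEE",  "note": "point-mutated pyruvate dehydrogenase E1; dxs bypass", "bypass_for": "dxs"},
    {"family_id": "hpnA",  "pathway_stage": "accessory",    "canonical_bgc_member": true,  "canonical_order": 1,    "similarity_threshold": 50, "query_label": "REF_HPNA",  "note": "BHPD-associated sugar epimerase; function unestablished"},
    {"family_id": "hpnB",  "pathway_stage": "accessory",    "canonical_bgc_member": true,  "canonical_order": 2,    "similarity_threshold": 50, "query_label": "REF_HPNB",  "note": "BHPD-associated glycosyl transferase; function unestablished"},
    {"family_id": "hpnC",  "pathway_stage": "squalene",     "canonical_bgc_member": true,  "canonical_order": 3,    "similarity_threshold": 50, "query_label": "REF_HPNC",  "note": "squalene synthase step"},
    {"family_id": "hpnD",  "pathway_stage": "squalene",     "canonical_bgc_member": true,  "canonical_order": 4,    "similarity_threshold": 50, "query_label": "REF_HPND",  "note": "presqualene diphosphate synthase"},
    {"family_id": "hpnE",  "pathway_stage": "squalene",     "canonical_bgc_member": true,  "canonical_order": 5,    "similarity_threshold": 50, "query_label": "REF_HPNE",  "note": "squalene-associated FAD-dependent reductase"},
    {"family_id": "shc",   "pathway_stage": "core_BHPD",    "canonical_bgc_member": true,  "canonical_order": 6,    "similarity_threshold": 50, "query_label": "REF_SHC",   "note": "squalene-hopene cyclase (HpnF)"},
    {"family_id": "hpnG",  "pathway_stage": "core_BHPD",    "canonical_bgc_member": true,  "canonical_order": 7,    "similarity_threshold": 50, "query_label": "REF_HPNG",  "note": "adenosylhopane phosphorylase; removes the adenine moiety"},
    {"family_id": "hpnH",  "pathway_stage": "core_BHPD",    "canonical_bgc_member": true,  "canonical_order": 8,    "similarity_threshold": 50, "query_label": "REF_HPNH",  "note": "radical SAM adenosylhopane synthase; first committed C35 step"},
    {"family_id": "hpnI",  "pathway_stage": "CE_branch",    "canonical_bgc_member": true,  "canonical_order": 9,    "similarity_threshold": 50, "query_label": "REF_HPNI",  "note": "glycosyltransferase; BHT to BHT N-acetylglucosamine"},
    {"family_id": "hpnJ",  "pathway_stage": "CE_branch",    "canonical_bgc_member": true,  "canonical_order": 10,   "similarity_threshold": 50, "query_label": "REF_HPNJ",  "note": "radical SAM; BHT glucosamine to BHT cyclitol ether"},
    {"family_id": "hpnK",  "pathway_stage": "CE_branch",    "canonical_bgc_member": true,  "canonical_order": 11,   "similarity_threshold": 50, "query_label": "REF_HPNK",  "note": "deacetylase; BHT N-acetylglucosamine to BHT glucosamine"},
    {"family_id": "hpnL",  "pathway_stage": "accessory",    "canonical_bgc_member": true,  "canonical_order": 12,   "similarity_threshold": 50, "query_label": "REF_HPNL",  "note": "function unestablished"},
    {"family_id": "hpnM",  "pathway_stage": "transport",    "canonical_bgc_member": true,  "canonical_order": 13,   "similarity_threshold": 50, "query_label": "REF_HPNM",  "note": "possible hopanoid transport, low salinity"},
    {"family_id": "hpnN",  "pathway_stage": "transport",    "canonical_bgc_member": true,  "canonical_order": 14,   "similarity_threshold": 50, "query_label": "REF_HPNN",  "note": "integral membrane hopanoid transporter"},
    {"family_id": "hpnO",  "pathway_stage": "amino_branch", "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_HPNO",  "note": "aminotransferase; ribosylhopane to aminobacteriohopanetriol; typically outside the BGC"},
    {"family_id": "hpnP",  "pathway_stage": "methylation",  "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 55, "query_label": "REF_HPNP",  "note": "radical SAM C-2 methylase; stricter cutoff against other B12-binding radical SAM proteins"},
    {"family_id": "hpnR",  "pathway_stage": "methylation",  "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_HPNR",  "note": "radical SAM C-3 methylase"},
    {"family_id": "ths",   "pathway_stage": "tetrahymanol", "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_THS",   "note": "tetrahymanol synthase"},
    {"family_id": "desat", "pathway_stage": "desaturase",   "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_DESAT", "note": "sterol-desaturase-like protein; candidate BHPD desaturase, outside the BGC"},
    {"family_id": "hpnX",  "pathway_stage": "desaturase",   "canonical_bgc_member": false, "canonical_order": null, "similarity_threshold": 50, "query_label": "REF_HPNX",  "note": "Rhodomicrobium-type sterol desaturase family protein"}
  ]
}
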