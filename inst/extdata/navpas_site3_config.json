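{
  "comment": "Default analysis configuration for the cockroach Nav channel (cryo-EM structure 6A95, author numbering). The site_region transcribes the broad site-3 residue set spanning domains DI and DIV; s4_region holds the DIV S4 gating-charge arginines plus Leu1264; key_residues are the channel residues whose buried-surface percentage is reported individually.",
  "site_region": {
    "name": "site3",
    "members": [
      {"resno": 278}, {"resno": 279},
      {"resno": 281}, {"resno": 282}, {"resno": 283}, {"resno": 286},
      {"resno": 301}, {"resno": 303}, {"resno": 306}, {"resno": 307},
      {"resno": 329}, {"resno": 330}, {"resno": 331},
      {"resno": 345}, {"resno": 347}, {"resno": 358}, {"resno": 359},
      {"resno": 387}, {"resno": 388}, {"resno": 392},
      {"resno": 1601}, {"resno": 1602},
      {"resno": 1190}, {"resno": 1191}, {"resno": 1192}, {"resno": 1193},
      {"resno": 1194}, {"resno": 1196}, {"resno": 1199}, {"resno": 1200},
      {"resno": 1202}, {"resno": 1203}, {"resno": 1204}, {"resno": 1206},
      {"resno": 1247}, {"resno": 1248},
      {"resno": 1252}, {"resno": 1253}, {"resno": 1254}, {"resno": 1255},
      {"resno": 1256}, {"resno": 1257}, {"resno": 1258}, {"resno": 1259},
      {"resno": 1261}, {"resno": 1262},
      {"resno": 1264}, {"resno": 1265}, {"resno": 1268}
    ]
  },
  "s4_region": {
    "name": "S4",
    "members": [{"resno": 1264}, {"resno": 1265}, {"resno": 1268}]
  },
  "glycan_region": {"name": "glycans", "resnames": ["NAG", "BMA", "MAN"]},
  "key_residues": [{"resno": 1255}, {"resno": 1265}, {"resno": 1268}],
  "probe": 1.4,
  "n_points": 960
}
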