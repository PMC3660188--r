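[
  {
    "comment": "Curated, editable approximations of recurrent Y-microdeletion STS-absence patterns expressed over the bundled 51-marker panel. Membership per class is a synthesis of the Y-microdeletion mapping literature, not a machine-readable published table: adapt it to your own marker set. 'absent' markers must all be missing and 'flanks' all present for a class to be called.",
    "class": "AZFa",
    "absent": ["sY1317", "sY1316", "sY1234"],
    "flanks": ["sY1250", "sY1231"]
  },
  {
    "class": "P5/proximal-P1",
    "absent": ["sY121", "sY1322", "sY280", "sY1233", "sY627", "sY1161", "sY1197"],
    "flanks": ["sY1234", "sY254"]
  },
  {
    "class": "P5/distal-P1",
    "absent": ["sY121", "sY1322", "sY280", "sY1233", "sY627", "sY1161", "sY1197", "sY1258", "sY1035", "sY1318", "sY254"],
    "flanks": ["sY1234", "sY1201"]
  },
  {
    "class": "AZFc",
    "absent": ["sY254", "sY1318", "sY1035", "sY1291", "sY1191", "sY1263", "sY1206"],
    "flanks": ["sY1258", "sY1201"]
  },
  {
    "class": "gr/gr",
    "absent": ["sY1291"],
    "flanks": ["sY1191", "sY254"]
  },
  {
    "class": "b2/b3",
    "absent": ["sY1191"],
    "flanks": ["sY1291", "sY254"]
  },
  {
    "class": "b1/b2",
    "absent": ["sY1258"],
    "flanks": ["sY1191", "sY1291", "sY254"]
  },
  {
    "class": "TSPY-TSPY",
    "absent": ["sY1250", "sY1256"],
    "flanks": ["sY276", "sY1251"]
  }
]
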