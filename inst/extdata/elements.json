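{
  "elements": [
    {"code": "B",    "name": "brow tine",                      "category": "tine",    "pocock_code": "a1", "requires": []},
    {"code": "L",    "name": "lower beam",                     "category": "beam",    "pocock_code": "p1", "requires": []},
    {"code": "T",    "name": "trez tine",                      "category": "tine",    "pocock_code": "a2", "requires": ["L"]},
    {"code": "H",    "name": "higher beam",                    "category": "beam",    "pocock_code": "p2", "requires": ["L"]},
    {"code": "F",    "name": "frontal tine",                   "category": "tine",    "pocock_code": "a2", "requires": ["L"]},
    {"code": "U",    "name": "upper beam",                     "category": "beam",    "pocock_code": "p2", "requires": ["L"]},
    {"code": "Z",    "name": "bez tine",                       "category": "tine",    "pocock_code": null, "requires": ["L"]},
    {"code": "M",    "name": "medial tine",                    "category": "tine",    "pocock_code": null, "requires": ["L"]},
    {"code": "BWP",  "name": "brow process",                   "category": "process", "pocock_code": null, "requires": ["B"]},
    {"code": "BI",   "name": "brow-inner tine",                "category": "tine",    "pocock_code": null, "requires": ["B"]},
    {"code": "BO",   "name": "brow-outer tine",                "category": "tine",    "pocock_code": null, "requires": ["B"]},
    {"code": "C",    "name": "cacuminal tine",                 "category": "tine",    "pocock_code": null, "requires": ["L"]},
    {"code": "PCs",  "name": "pre-cacuminal tines",            "category": "tine",    "pocock_code": null, "requires": ["L"]},
    {"code": "CI",   "name": "crown-inner tine",               "category": "tine",    "pocock_code": null, "requires": ["H"]},
    {"code": "CO",   "name": "crown-outer tine",               "category": "tine",    "pocock_code": null, "requires": ["H"]},
    {"code": "CB",   "name": "crown-back tine",                "category": "tine",    "pocock_code": null, "requires": ["H"]},
    {"code": "CBI",  "name": "crown-back-inner tine",          "category": "tine",    "pocock_code": null, "requires": ["CB"]},
    {"code": "CBB",  "name": "crown-back-back tine",           "category": "tine",    "pocock_code": null, "requires": ["CB"]},
    {"code": "G",    "name": "guard tine",                     "category": "tine",    "pocock_code": null, "requires": ["H"]},
    {"code": "V",    "name": "vertical beam",                  "category": "beam",    "pocock_code": null, "requires": ["L"]},
    {"code": "V1",   "name": "vertical-first tine",            "category": "tine",    "pocock_code": null, "requires": ["V"]},
    {"code": "K",    "name": "back beam",                      "category": "beam",    "pocock_code": null, "requires": ["V"]},
    {"code": "K1",   "name": "back-first tine",                "category": "tine",    "pocock_code": null, "requires": ["K"]},
    {"code": "R",    "name": "rear tine",                      "category": "tine",    "pocock_code": null, "requires": ["U"]},
    {"code": "TA",   "name": "terminal-anterior tine",         "category": "tine",    "pocock_code": null, "requires": ["U"]},
    {"code": "TP",   "name": "terminal-posterior tine",        "category": "tine",    "pocock_code": null, "requires": ["U"]},
    {"code": "TPAs", "name": "terminal-posterior-anterior tines", "category": "tine", "pocock_code": null, "requires": ["TP"]},
    {"code": "FPs",  "name": "frontal-posterior tines",        "category": "tine",    "pocock_code": null, "requires": ["F"]},
    {"code": "U1",   "name": "upper-1st tine",                 "category": "tine",    "pocock_code": null, "requires": ["U"]},
    {"code": "U1A",  "name": "upper-1st-anterior tine",        "category": "tine",    "pocock_code": null, "requires": ["U1"]},
    {"code": "U1P",  "name": "upper-1st-posterior tine",       "category": "tine",    "pocock_code": null, "requires": ["U1"]},
    {"code": "U2",   "name": "upper-2nd tine",                 "category": "tine",    "pocock_code": null, "requires": ["U"]},
    {"code": "U3",   "name": "upper-3rd tine",                 "category": "tine",    "pocock_code": null, "requires": ["U"]}
  ],
  "skull_indices": [
    {"code": "SR",   "description": "supraorbital ridge on the pedicle"},
    {"code": "TR",   "description": "temporal ridge on the pedicle"},
    {"code": "IFST", "description": "impression of the frontal branch of the superficial temporal artery (medial branch)"},
    {"code": "SPO",  "description": "reaching the superior-posterior margin of the orbit"},
    {"code": "LMOF", "description": "reaching the lateral margin of the origin of the frontoscutular muscle, to the posterior margin of the orbit"},
    {"code": "PEOI", "description": "reaching the posterior extremity of the origin of the interscutular muscle"},
    {"code": "BN",   "description": "boundary of the supraorbital and temporal nerve areas"}
  ]
}
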