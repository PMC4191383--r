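[
  {"short_name": "C",    "full_name": "cytidine",                 "formula": "C9H13N3O5",   "parent": null, "canonical": true,  "sugar": "ribose",        "rt_window": [1.5, 3.5]},
  {"short_name": "U",    "full_name": "uridine",                  "formula": "C9H12N2O6",   "parent": null, "canonical": true,  "sugar": "ribose",        "rt_window": [2.5, 4.5]},
  {"short_name": "G",    "full_name": "guanosine",                "formula": "C10H13N5O5",  "parent": null, "canonical": true,  "sugar": "ribose",        "rt_window": [5.5, 7.5]},
  {"short_name": "A",    "full_name": "adenosine",                "formula": "C10H13N5O4",  "parent": null, "canonical": true,  "sugar": "ribose",        "rt_window": [8.0, 10.0]},
  {"short_name": "Y",    "full_name": "pseudouridine",            "formula": "C9H12N2O6",   "parent": "U",  "canonical": false, "sugar": "none",          "rt_window": [1.0, 2.5],
   "transition": [245.077, 209.056],
   "note": "C-glycoside: no ribose neutral loss; transition is the double water loss and must be supplied explicitly"},
  {"short_name": "m5C",  "full_name": "5-methylcytidine",         "formula": "C10H15N3O5",  "parent": "C",  "canonical": false, "sugar": "ribose",        "rt_window": [3.0, 5.0]},
  {"short_name": "Cm",   "full_name": "2'-O-methylcytidine",      "formula": "C10H15N3O5",  "parent": "C",  "canonical": false, "sugar": "methylribose",  "rt_window": [3.5, 5.5]},
  {"short_name": "s4U",  "full_name": "4-thiouridine",            "formula": "C9H12N2O5S",  "parent": "U",  "canonical": false, "sugar": "ribose",        "rt_window": [7.0, 9.0]},
  {"short_name": "m5s2U","full_name": "5-methyl-2-thiouridine",   "formula": "C10H14N2O5S", "parent": "U",  "canonical": false, "sugar": "ribose",        "rt_window": [9.0, 11.0]},
  {"short_name": "m7G",  "full_name": "7-methylguanosine",        "formula": "C11H15N5O5",  "parent": "G",  "canonical": false, "sugar": "ribose",        "rt_window": [4.5, 6.5]},
  {"short_name": "Am",   "full_name": "2'-O-methyladenosine",     "formula": "C11H15N5O4",  "parent": "A",  "canonical": false, "sugar": "methylribose",  "rt_window": [11.0, 13.0]},
  {"short_name": "m1A",  "full_name": "1-methyladenosine",        "formula": "C11H15N5O4",  "parent": "A",  "canonical": false, "sugar": "ribose",        "rt_window": [2.0, 4.0]},
  {"short_name": "m62A", "full_name": "N6,N6-dimethyladenosine",  "formula": "C12H17N5O4",  "parent": "A",  "canonical": false, "sugar": "ribose",        "rt_window": [13.5, 15.5]},
  {"short_name": "I",    "full_name": "inosine",                  "formula": "C10H12N4O5",  "parent": "A",  "canonical": false, "sugar": "ribose",        "rt_window": [5.0, 7.0]},
  {"short_name": "m5U",  "full_name": "5-methyluridine",          "formula": "C10H14N2O6",  "parent": "U",  "canonical": false, "sugar": "ribose",        "rt_window": [5.5, 7.5]},
  {"short_name": "Um",   "full_name": "2'-O-methyluridine",       "formula": "C10H14N2O6",  "parent": "U",  "canonical": false, "sugar": "methylribose",  "rt_window": [6.0, 8.0]},
  {"short_name": "Gm",   "full_name": "2'-O-methylguanosine",     "formula": "C11H15N5O5",  "parent": "G",  "canonical": false, "sugar": "methylribose",  "rt_window": [8.0, 10.0]},
  {"short_name": "m6A",  "full_name": "N6-methyladenosine",       "formula": "C11H15N5O4",  "parent": "A",  "canonical": false, "sugar": "ribose",        "rt_window": [12.0, 14.0]},
  {"short_name": "D",    "full_name": "dihydrouridine",           "formula": "C9H14N2O6",   "parent": "U",  "canonical": false, "sugar": "ribose",        "rt_window": [1.0, 2.5],
   "no_external_calibration": true},
  {"short_name": "m3C",  "full_name": "3-methylcytidine",         "formula": "C10H15N3O5",  "parent": "C",  "canonical": false, "sugar": "ribose",        "rt_window": [2.5, 4.5],
   "no_external_calibration": true},
  {"short_name": "m2A",  "full_name": "2-methyladenosine",        "formula": "C11H15N5O4",  "parent": "A",  "canonical": false, "sugar": "ribose",        "rt_window": [10.0, 12.0],
   "no_external_calibration": true},
  {"short_name": "m1G",  "full_name": "1-methylguanosine",        "formula": "C11H15N5O5",  "parent": "G",  "canonical": false, "sugar": "ribose",        "rt_window": [6.5, 8.5],
   "no_external_calibration": true},
  {"short_name": "m2G",  "full_name": "2-methylguanosine",        "formula": "C11H15N5O5",  "parent": "G",  "canonical": false, "sugar": "ribose",        "rt_window": [7.0, 9.0],
   "no_external_calibration": true}
]
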