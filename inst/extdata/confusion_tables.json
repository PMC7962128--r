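{
  "comment": "Per-model confusion counts from the published 4-fold clinical validation of the two-part stroke-gait network. Detection: one block per class treated as positive (fold size 1000 each). Classification: five output blocks per model; block totals equal the model's classification fold size (502, 508, 499, 500 for models 1-4 after the documented correction). The 'corrections' entry records the single typographic fix applied when loading with corrected=TRUE.",
  "detection": [
    {"model": 1, "label": "normal", "tp": 496, "fp": 3, "fn": 4, "tn": 497},
    {"model": 1, "label": "stroke", "tp": 497, "fp": 5, "fn": 3, "tn": 495},
    {"model": 2, "label": "normal", "tp": 495, "fp": 2, "fn": 5, "tn": 498},
    {"model": 2, "label": "stroke", "tp": 500, "fp": 8, "fn": 0, "tn": 492},
    {"model": 3, "label": "normal", "tp": 498, "fp": 2, "fn": 2, "tn": 498},
    {"model": 3, "label": "stroke", "tp": 497, "fp": 2, "fn": 3, "tn": 498},
    {"model": 4, "label": "normal", "tp": 496, "fp": 3, "fn": 4, "tn": 497},
    {"model": 4, "label": "stroke", "tp": 497, "fp": 3, "fn": 3, "tn": 497}
  ],
  "classification": [
    {"model": 1, "label": "stroke", "tp": 497, "fp": 5, "fn": 0, "tn": 0},
    {"model": 1, "label": "drop_foot", "tp": 77, "fp": 5, "fn": 2, "tn": 418},
    {"model": 1, "label": "circumduction", "tp": 77, "fp": 0, "fn": 20, "tn": 405},
    {"model": 1, "label": "hip_hiking", "tp": 154, "fp": 10, "fn": 17, "tn": 321},
    {"model": 1, "label": "back_knee", "tp": 105, "fp": 8, "fn": 21, "tn": 368},
    {"model": 2, "label": "stroke", "tp": 500, "fp": 8, "fn": 0, "tn": 0},
    {"model": 2, "label": "drop_foot", "tp": 96, "fp": 7, "fn": 4, "tn": 401},
    {"model": 2, "label": "circumduction", "tp": 98, "fp": 11, "fn": 0, "tn": 399},
    {"model": 2, "label": "hip_hiking", "tp": 178, "fp": 14, "fn": 4, "tn": 312},
    {"model": 2, "label": "back_knee", "tp": 112, "fp": 5, "fn": 20, "tn": 371},
    {"model": 3, "label": "stroke", "tp": 497, "fp": 2, "fn": 0, "tn": 0},
    {"model": 3, "label": "drop_foot", "tp": 101, "fp": 4, "fn": 6, "tn": 388},
    {"model": 3, "label": "circumduction", "tp": 113, "fp": 2, "fn": 4, "tn": 380},
    {"model": 3, "label": "hip_hiking", "tp": 197, "fp": 5, "fn": 10, "tn": 287},
    {"model": 3, "label": "back_knee", "tp": 131, "fp": 8, "fn": 1, "tn": 359},
    {"model": 4, "label": "stroke", "tp": 497, "fp": 3, "fn": 0, "tn": 0},
    {"model": 4, "label": "drop_foot", "tp": 89, "fp": 7, "fn": 4, "tn": 400},
    {"model": 4, "label": "circumduction", "tp": 98, "fp": 9, "fn": 4, "tn": 489},
    {"model": 4, "label": "hip_hiking", "tp": 168, "fp": 13, "fn": 5, "tn": 314},
    {"model": 4, "label": "back_knee", "tp": 123, "fp": 4, "fn": 19, "tn": 354}
  ],
  "corrections": [
    {"model": 4, "task": "classification", "label": "circumduction",
     "field": "tn", "printed": 489, "corrected": 389,
     "reason": "printed block sums to 600, not the model's fold size 500; the corrected value restores the fold size and the model's published summary accuracy 0.9728"}
  ]
}
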