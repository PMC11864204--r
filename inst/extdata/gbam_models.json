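{
  "comment": "Parameter sets of the acute Ni generalized bioavailability models (gBAM). pH segments are (lower, upper, slope); the pH effect on the exponent accumulates segment-by-segment from the first segment's lower bound, which keeps the predicted free-ion LC50 continuous in pH. The average invertebrate high-pH slope is stored at full precision 1.00635 (mean of 1.095 and 0.9177) and displays as 1.006.",
  "models": {
    "avg_invertebrate": {
      "label": "pH extended average invertebrate model",
      "logk_cabl": 3.80,
      "logk_mgbl": 3.32,
      "ph_segments": [[5.6, 8.0, 0.0], [8.0, 8.9, 1.00635]],
      "applicability": {"ph": [5.6, 8.9], "hardness": [6.2, 339]}
    },
    "algae": {
      "label": "pH extended algae model",
      "logk_cabl": null,
      "logk_mgbl": 3.30,
      "ph_segments": [[5.7, 8.2, 0.143], [8.2, 8.7, 0.906]],
      "applicability": {"ph": [5.7, 8.7], "hardness": [6.3, 315]}
    },
    "fish": {
      "label": "fish model",
      "logk_cabl": 3.60,
      "logk_mgbl": 3.60,
      "ph_segments": [[5.5, 8.8, 0.324]],
      "applicability": {"ph": [5.5, 8.8], "hardness": [12, 290]}
    },
    "d_magna": {
      "label": "Daphnia magna model",
      "logk_cabl": 3.10,
      "logk_mgbl": 2.47,
      "ph_segments": [[5.7, 8.1, 0.0]],
      "applicability": {"ph": [5.7, 8.1], "hardness": [6.2, 292]}
    },
    "d_pulex": {
      "label": "Daphnia pulex model",
      "logk_cabl": 4.20,
      "logk_mgbl": 3.60,
      "ph_segments": [[5.6, 8.3, 0.0]],
      "applicability": {"ph": [5.6, 8.3], "hardness": [16.0, 161]}
    },
    "c_dubia": {
      "label": "Ceriodaphnia dubia model",
      "logk_cabl": 3.30,
      "logk_mgbl": 3.30,
      "ph_segments": [[6.3, 8.1, 0.0]],
      "applicability": {"ph": [6.3, 8.1], "hardness": [15.0, 253]}
    }
  }
}
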