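{
  "name": "lu177-6w",
  "description": "Six contiguous Lu-177 acquisition energy windows (18-680 keV) with 3W/4W/6W wide-spectrum combinations and TEW/DEW scatter correction. Limits are the vendor-reported integer keV values.",
  "windows": [
    {"name": "PP", "label": "Photopeak",         "centre_keV": 208,  "width_percent": 20,  "lower_keV": 187, "upper_keV": 229},
    {"name": "LS", "label": "Lower Scatter",     "centre_keV": null, "width_percent": 10,  "lower_keV": 166, "upper_keV": 187},
    {"name": "US", "label": "Upper Scatter",     "centre_keV": null, "width_percent": 10,  "lower_keV": 229, "upper_keV": 250},
    {"name": "G1", "label": "General Scatter 1", "centre_keV": 465,  "width_percent": 93,  "lower_keV": 250, "upper_keV": 680},
    {"name": "G2", "label": "General Scatter 2", "centre_keV": 111,  "width_percent": 100, "lower_keV": 55,  "upper_keV": 166},
    {"name": "G3", "label": "General Scatter 3", "centre_keV": 37,   "width_percent": 100, "lower_keV": 18,  "upper_keV": 55}
  ],
  "combinations": {
    "photopeak": ["PP"],
    "3W": ["PP", "LS", "G2"],
    "4W": ["PP", "LS", "US", "G2"],
    "6W": ["PP", "LS", "US", "G1", "G2", "G3"]
  },
  "scatter_windows": {
    "TEW": ["LS", "US"],
    "DEW": ["LS"]
  }
}
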