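{
  "sensitivity_weight": 2,
  "per_label": [
    {"label_id": 1, "label": "humerus", "metric": "DCA", "orientation": "higher_is_better", "threshold": 0.97, "r_squared": null, "youden": null, "sensitivity": null, "specificity": null},
    {"label_id": 2, "label": "scapula", "metric": "DCA", "orientation": "higher_is_better", "threshold": 0.94, "r_squared": null, "youden": null, "sensitivity": null, "specificity": null},
    {"label_id": 3, "label": "supraspinatus", "metric": "DCA", "orientation": "higher_is_better", "threshold": 0.92, "r_squared": null, "youden": null, "sensitivity": null, "specificity": null},
    {"label_id": 4, "label": "subscapularis", "metric": "DCA", "orientation": "higher_is_better", "threshold": 0.91, "r_squared": null, "youden": null, "sensitivity": null, "specificity": null},
    {"label_id": 5, "label": "infraspinatus", "metric": "DCA", "orientation": "higher_is_better", "threshold": 0.93, "r_squared": null, "youden": null, "sensitivity": null, "specificity": null},
    {"label_id": 6, "label": "teres_minor", "metric": "DCA", "orientation": "higher_is_better", "threshold": 0.94, "r_squared": null, "youden": null, "sensitivity": null, "specificity": null}
  ]
}
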