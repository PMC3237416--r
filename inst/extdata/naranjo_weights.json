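{
  "name": "Naranjo ADR probability scale",
  "version": "1981",
  "questions": [
    {"id": "Q1", "text": "Are there previous conclusive reports on this reaction?", "yes": 1, "no": 0, "unknown": 0},
    {"id": "Q2", "text": "Did the adverse event appear after the suspected drug was administered?", "yes": 2, "no": -1, "unknown": 0},
    {"id": "Q3", "text": "Did the adverse reaction improve when the drug was discontinued or a specific antagonist was administered?", "yes": 1, "no": 0, "unknown": 0},
    {"id": "Q4", "text": "Did the adverse reaction reappear after the drug was readministered?", "yes": 2, "no": -1, "unknown": 0},
    {"id": "Q5", "text": "Are there alternative causes (other than the drug) that could on their own have caused the reaction?", "yes": -1, "no": 2, "unknown": 0},
    {"id": "Q6", "text": "Did the reaction reappear when a placebo was given?", "yes": -1, "no": 1, "unknown": 0},
    {"id": "Q7", "text": "Was the drug detected in the blood (or other fluids) in concentrations known to be toxic?", "yes": 1, "no": 0, "unknown": 0},
    {"id": "Q8", "text": "Was the reaction more severe when the dose was increased, or less severe when the dose was decreased?", "yes": 1, "no": 0, "unknown": 0},
    {"id": "Q9", "text": "Did the patient have a similar reaction to the same or similar drugs in any previous exposure?", "yes": 1, "no": 0, "unknown": 0},
    {"id": "Q10", "text": "Was the adverse event confirmed by any objective evidence?", "yes": 1, "no": 0, "unknown": 0}
  ],
  "boundaries": {"unlikely_max": 0, "possible_max": 4, "probable_max": 8}
}
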