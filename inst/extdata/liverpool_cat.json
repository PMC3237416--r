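{
  "metadata": {
    "name": "Liverpool ADR causality assessment tool",
    "version": "1.0",
    "notes": [
      "Transcription of the published flowchart: routing is dichotomous except at the alternative-cause question, which offers an 'unsure' option prompting the assessor to seek further evidence.",
      "A verdict of definite is reachable only through an affirmative answer at the re-challenge / previous-reaction question (tagged rechallenge_gate).",
      "Routing choices not fixed by the published text and recorded here: an unsure alternative-cause answer routes through the objective-evidence question and caps at possible when no supporting evidence is found; when the drug was never withdrawn the de-challenge question is skipped and assessment continues at the re-challenge question; previous conclusive reports and a dose-response relationship separate probable from possible when re-challenge is negative or absent."
    ]
  },
  "root": "temporal",
  "nodes": [
    {
      "id": "temporal",
      "prompt": "Was the drug administered before the adverse event occurred?",
      "routes": {"yes": "alt_cause", "no": "leaf_unlikely_temporal"}
    },
    {
      "id": "alt_cause",
      "prompt": "Is an alternative cause (for example the underlying disease or another drug) more likely than the suspected drug to have caused the event?",
      "routes": {"yes": "leaf_unlikely_alt", "no": "withdrawn", "unsure": "evidence"}
    },
    {
      "id": "evidence",
      "prompt": "Is there objective evidence of a likely drug-related mechanism (for example toxic drug concentrations or characteristic investigation findings)?",
      "routes": {"yes": "withdrawn", "no": "leaf_possible_evidence"}
    },
    {
      "id": "withdrawn",
      "prompt": "Was the drug withdrawn or the dose reduced?",
      "routes": {"yes": "improved", "no": "rechallenge"}
    },
    {
      "id": "improved",
      "prompt": "Did the event improve after withdrawal or dose reduction (allowing for reactions with long-lasting sequelae)?",
      "routes": {"yes": "rechallenge", "no": "leaf_unlikely_dechallenge"}
    },
    {
      "id": "rechallenge",
      "prompt": "Did the event recur on re-administration of the drug, or has the patient had a similar reaction to the same drug on a previous exposure?",
      "tags": {"rechallenge_gate": true},
      "routes": {"yes": "leaf_definite", "no": "reports"}
    },
    {
      "id": "reports",
      "prompt": "Are there previous conclusive reports of this reaction with the suspected drug, or a dose-response relationship between drug and event?",
      "routes": {"yes": "leaf_probable", "no": "leaf_possible_final"}
    }
  ],
  "leaves": [
    {"id": "leaf_unlikely_temporal", "category": "unlikely"},
    {"id": "leaf_unlikely_alt", "category": "unlikely"},
    {"id": "leaf_unlikely_dechallenge", "category": "unlikely"},
    {"id": "leaf_possible_evidence", "category": "possible"},
    {"id": "leaf_possible_final", "category": "possible"},
    {"id": "leaf_probable", "category": "probable"},
    {"id": "leaf_definite", "category": "definite"}
  ]
}
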