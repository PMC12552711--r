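{
  "name": "GAD-7 (first-person wording)",
  "scale_min": 1,
  "scale_max": 4,
  "items": [
    {"item_id": "GAD1", "text": "I feel nervous, anxious, or on edge", "factor": "Anxiety"},
    {"item_id": "GAD2", "text": "I am not able to stop or control worrying", "factor": "Anxiety"},
    {"item_id": "GAD3", "text": "I worry too much about different things", "factor": "Anxiety"},
    {"item_id": "GAD4", "text": "I have trouble relaxing", "factor": "Anxiety"},
    {"item_id": "GAD5", "text": "I am so restless that it is hard to sit still", "factor": "Anxiety"},
    {"item_id": "GAD6", "text": "I become easily annoyed or irritable", "factor": "Anxiety"},
    {"item_id": "GAD7", "text": "I feel afraid, as if something awful might happen", "factor": "Anxiety"}
  ]
}
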