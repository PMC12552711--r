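{
  "name": "PHQ-9 (first-person wording)",
  "scale_min": 1,
  "scale_max": 4,
  "items": [
    {"item_id": "PHQ1", "text": "I have little interest or pleasure in doing things", "factor": "Depression"},
    {"item_id": "PHQ2", "text": "I feel down, depressed, or hopeless", "factor": "Depression"},
    {"item_id": "PHQ3", "text": "I have trouble falling or staying asleep, or I sleep too much", "factor": "Depression"},
    {"item_id": "PHQ4", "text": "I feel tired or have little energy", "factor": "Depression"},
    {"item_id": "PHQ5", "text": "I have a poor appetite or I overeat", "factor": "Depression"},
    {"item_id": "PHQ6", "text": "I feel bad about myself, or that I am a failure, or that I have let myself or my family down", "factor": "Depression"},
    {"item_id": "PHQ7", "text": "I have trouble concentrating on things, such as reading the newspaper or watching television", "factor": "Depression"},
    {"item_id": "PHQ8", "text": "I move or speak so slowly that other people could notice, or I am so fidgety or restless that I move around a lot more than usual", "factor": "Depression"},
    {"item_id": "PHQ9", "text": "I have thoughts that I would be better off dead or of hurting myself in some way", "factor": "Depression"}
  ]
}
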