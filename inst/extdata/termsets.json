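{
  "five": {
    "id": "five",
    "labels": ["fail", "pass", "good", "very good", "excellent"]
  },
  "seven": {
    "id": "seven",
    "labels": ["very poor", "poor", "slightly poor", "fair", "slightly good", "good", "very good"]
  },
  "seven_importance": {
    "id": "seven_importance",
    "labels": ["very unimportant", "unimportant", "slightly unimportant", "middle", "slightly important", "important", "very important"]
  }
}
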