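{
  "description": "Index-system optimization plan adopted in the HTCC case study: two indicators screened out, three pairwise indicator integrations, and the network-quality dimension folded into system quality.",
  "indicator_merges": [
    {
      "sources": ["process_convenience", "operational_ease_of_use"],
      "target": {"id": "operational_convenience", "name": "Operational Convenience", "dimension_id": "system_quality"}
    },
    {
      "sources": ["doctor_patient_ratio", "consultation_visitors"],
      "target": {"id": "doctor_patient_ratio_rationality", "name": "Rationality of Doctor-Patient Ratio", "dimension_id": "structure_quality"}
    },
    {
      "sources": ["treatment_effect", "re_consultation_rate"],
      "target": {"id": "treatment_effect", "name": "Treatment Effect", "dimension_id": "outcome_quality"}
    }
  ],
  "dimension_merges": [
    {
      "sources": ["network_quality", "system_quality"],
      "target": {"id": "system_quality", "name": "System Quality"}
    }
  ]
}
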