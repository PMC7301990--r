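indicator_id,name,dimension_id,dimension_name
network_service_provider,Network Service Provider,network_quality,Network Quality
network_rate,Network Rate,network_quality,Network Quality
video_resolution,Video Resolution,system_quality,System Quality
equipment_quality,Equipment Quality,system_quality,System Quality
process_convenience,Process Convenience,system_quality,System Quality
operational_ease_of_use,Operational Ease of Use,system_quality,System Quality
doctor_patient_ratio,Doctor-Patient Ratio,structure_quality,Structure Quality
consultation_visitors,Consultation Visitors,structure_quality,Structure Quality
turnover_rates_consulting_room,Turnover Rates of Consulting Room,structure_quality,Structure Quality
charges,Charges,structure_quality,Structure Quality
purpose_of_application,Purpose of Application,interaction_quality,Interaction Quality
appointment_channel,Appointment Channel,interaction_quality,Interaction Quality
waiting_time,Waiting Time,interaction_quality,Interaction Quality
regional_hospital_level,Regional Hospital Level,interaction_quality,Interaction Quality
data_integrity,Data Integrity,interaction_quality,Interaction Quality
regional_doctor_level,Regional Doctor Level,interaction_quality,Interaction Quality
expert_level,Expert Level,interaction_quality,Interaction Quality
operators_attitude,Operators' Attitude,interaction_quality,Interaction Quality
experts_attitude,Experts' Attitude,interaction_quality,Interaction Quality
consultation_duration,Consultation Duration,interaction_quality,Interaction Quality
information_usefulness,Information Usefulness,outcome_quality,Outcome Quality
diagnostic_coincidence_rate,Diagnostic Coincidence Rate,outcome_quality,Outcome Quality
treatment_effect,Treatment Effect,outcome_quality,Outcome Quality
re_consultation_rate,Re-consultation Rate,outcome_quality,Outcome Quality
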