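indicator_id,name,dimension_id,a,b,c,d,note
network_service_provider,Network Service Provider,network_quality,0.206,0.301,0.431,0.527,b printed as 0301; read as 0.301
network_rate,Network Rate,network_quality,0.512,0.607,0.713,0.808,
video_resolution,Video Resolution,system_quality,0.608,0.703,0.823,0.896,
equipment_quality,Equipment Quality,system_quality,0.648,0.743,0.848,0.914,
process_convenience,Process Convenience,system_quality,0.412,0.507,0.602,0.697,
operational_ease_of_use,Operational Ease of Use,system_quality,0.392,0.487,0.582,0.677,
doctor_patient_ratio,Doctor-Patient Ratio,structure_quality,0.573,0.668,0.773,0.861,
consultation_visitors,Consultation Visitors,structure_quality,0.432,0.528,0.623,0.718,
turnover_rates_consulting_room,Turnover Rates of Consulting Room,structure_quality,0.558,0.653,0.758,0.846,
charges,Charges,structure_quality,0.563,0.659,0.764,0.852,
purpose_of_application,Purpose of Application,interaction_quality,0.573,0.668,0.798,0.879,
appointment_channel,Appointment Channel,interaction_quality,0.226,0.321,0.462,0.557,
waiting_time,Waiting Time,interaction_quality,0.578,0.673,0.794,0.874,
regional_hospital_level,Regional Hospital Level,interaction_quality,0.643,0.738,0.864,0.932,c/d printed as 0.864.0.932; read as two values
data_integrity,Data Integrity,interaction_quality,0.533,0.628,0.733,0.828,
regional_doctor_level,Regional Doctor Level,interaction_quality,0.568,0.663,0.758,0.854,
expert_level,Expert Level,interaction_quality,0.810,0.905,1.000,1.000,
operators_attitude,Operators' Attitude,interaction_quality,0.568,0.663,0.758,0.854,
experts_attitude,Experts' Attitude,interaction_quality,0.618,0.713,0.829,0.909,
consultation_duration,Consultation Duration,interaction_quality,0.533,0.628,0.723,0.811,
information_usefulness,Information Usefulness,outcome_quality,0.649,0.744,0.839,0.915,
diagnostic_coincidence_rate,Diagnostic Coincidence Rate,outcome_quality,0.668,0.764,0.859,0.919,
treatment_effect,Treatment Effect,outcome_quality,0.810,0.905,1.000,1.000,
re_consultation_rate,Re-consultation Rate,outcome_quality,0.427,0.522,0.617,0.712,
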