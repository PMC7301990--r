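indicator_code,dimension_code,name,name_source,ap_a,ap_b,ap_c,ap_d,ae_a,ae_b,ae_c,ae_d,P,E,gap
C11,C1,Network Rate,named,0.612,0.689,0.766,0.843,0.614,0.691,0.768,0.845,0.728,0.730,-0.002
C12,C1,Video Resolution,named,0.619,0.696,0.773,0.850,0.615,0.692,0.769,0.846,0.735,0.731,0.004
C13,C1,Equipment Quality,named,0.611,0.688,0.765,0.842,0.610,0.687,0.763,0.840,0.727,0.725,0.002
C14,C1,Operational Convenience,named,0.587,0.664,0.741,0.818,0.605,0.682,0.758,0.835,0.715,0.720,-0.005
C21,C2,Rationality of Doctor-Patient Ratio,positional,0.604,0.681,0.758,0.835,0.605,0.682,0.758,0.835,0.720,0.720,-0.001
C22,C2,Turnover Rates of Consulting Room,named,0.560,0.637,0.713,0.790,0.590,0.667,0.744,0.821,0.675,0.706,-0.031
C23,C2,Charges,named,0.578,0.655,0.732,0.809,0.604,0.681,0.757,0.834,0.694,0.719,-0.026
C31,C3,Purpose of Application,positional,0.599,0.676,0.753,0.830,0.594,0.671,0.748,0.825,0.715,0.710,0.005
C32,C3,Waiting Time,positional,0.609,0.686,0.763,0.840,0.614,0.691,0.768,0.845,0.725,0.730,-0.005
C33,C3,Regional Hospital Level,positional,0.585,0.662,0.739,0.816,0.581,0.658,0.734,0.811,0.701,0.696,0.004
C34,C3,Data Integrity,positional,0.622,0.699,0.776,0.853,0.616,0.693,0.770,0.847,0.738,0.732,0.006
C35,C3,Regional Doctor Level,positional,0.593,0.670,0.747,0.824,0.612,0.689,0.766,0.843,0.709,0.728,-0.019
C36,C3,Expert Level,positional,0.643,0.720,0.797,0.874,0.631,0.708,0.785,0.862,0.759,0.747,0.012
C37,C3,Operators' Attitude,named,0.590,0.666,0.743,0.819,0.620,0.697,0.774,0.851,0.705,0.736,-0.031
C38,C3,Experts' Attitude,named,0.590,0.667,0.744,0.821,0.615,0.692,0.769,0.846,0.706,0.731,-0.025
C39,C3,Consultation Duration,named,0.537,0.614,0.691,0.768,0.569,0.646,0.723,0.780,0.653,0.681,-0.029
C41,C4,Information Usefulness,positional,0.626,0.703,0.780,0.857,0.589,0.666,0.743,0.820,0.742,0.705,0.037
C42,C4,Diagnostic Coincidence Rate,positional,0.627,0.704,0.781,0.858,0.591,0.668,0.745,0.822,0.743,0.707,0.036
C43,C4,Treatment Effect,positional,0.626,0.703,0.780,0.857,0.600,0.677,0.754,0.831,0.742,0.716,0.026
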