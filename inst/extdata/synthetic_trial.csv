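patient_id,arm,followup,event,cost,subgroup
P01,0,6.000,0,836.13,0
P02,0,3.888,0,369.12,0
P03,0,6.000,0,661.04,0
P04,0,2.462,1,748.00,0
P05,0,4.811,1,486.66,0
P06,0,4.671,0,1645.21,1
P07,0,1.727,0,335.19,1
P08,0,0.313,0,739.04,1
P09,0,3.829,1,1045.68,1
P10,0,2.459,1,816.53,1
P11,1,1.122,0,623.36,0
P12,1,6.000,0,678.20,0
P13,1,2.158,1,1595.04,0
P14,1,3.316,1,824.59,0
P15,1,1.841,0,931.90,0
P16,1,5.530,1,1849.11,1
P17,1,3.401,1,1319.63,1
P18,1,5.435,1,1430.52,1
P19,1,6.000,0,1862.93,1
P20,1,1.825,1,2228.25,1
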