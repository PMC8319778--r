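patient_id,week,phq9
P-imp-00001,0,13
P-imp-00001,3,10
P-imp-00001,6,11
P-imp-00001,9,3
P-imp-00001,12,6
P-imp-00002,0,12
P-imp-00002,3,10
P-imp-00002,6,11
P-imp-00002,9,3
P-imp-00002,12,0
P-imp-00003,0,11
P-imp-00003,3,8
P-imp-00003,6,5
P-imp-00003,9,7
P-imp-00003,12,3
P-imp-00004,0,15
P-imp-00004,3,12
P-imp-00004,6,8
P-imp-00004,9,8
P-imp-00004,12,2
P-imp-00005,0,13
P-imp-00005,3,9
P-imp-00005,6,9
P-imp-00005,9,6
P-imp-00005,12,3
P-non-00001,0,14
P-non-00001,3,15
P-non-00001,6,16
P-non-00001,9,13
P-non-00001,12,14
P-non-00002,0,16
P-non-00002,3,16
P-non-00002,6,13
P-non-00002,9,8
P-non-00002,12,11
P-non-00003,0,9
P-non-00003,3,12
P-non-00003,6,12
P-non-00003,9,9
P-non-00003,12,11
P-non-00004,0,11
P-non-00004,3,14
P-non-00004,6,11
P-non-00004,9,10
P-non-00004,12,13
P-non-00005,0,12
P-non-00005,3,12
P-non-00005,6,11
P-non-00005,9,11
P-non-00005,12,9
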