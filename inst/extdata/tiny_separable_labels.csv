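patient_id,outcome
T01,1
T02,1
T03,1
T04,1
T05,1
T06,1
T07,0
T08,0
T09,0
T10,0
T11,0
T12,0
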