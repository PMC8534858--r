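patient_id,code
T01,N100.
T01,B001.
T02,N100.
T02,B001.
T03,N100.
T03,B001.
T04,N100.
T04,B001.
T05,N100.
T05,B001.
T06,N100.
T06,B001.
T02,N100.
T04,N100.
T07,B001.
T08,B001.
T09,B001.
T10,B001.
T11,B001.
T12,B001.
T08,C002.
T10,C002.
T12,C002.
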