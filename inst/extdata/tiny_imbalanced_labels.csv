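patient_id,outcome
M01,0
M02,0
M03,0
M04,0
M05,0
M06,0
M07,0
M08,0
M09,0
M10,0
M11,0
M12,0
M13,0
M14,0
M15,0
M16,0
M17,0
M18,0
M19,0
M20,0
M21,0
M22,0
M23,0
M24,0
M25,0
M26,0
M27,0
M28,0
M29,0
M30,0
M31,0
M32,0
M33,0
M34,0
M35,0
M36,0
M37,0
M38,0
M39,0
M40,0
M41,0
M42,0
M43,0
M44,0
M45,0
M46,0
M47,0
M48,0
M49,1
M50,1
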