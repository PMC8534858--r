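patient_id,code
M01,B001.
M02,B001.
M03,B001.
M04,B001.
M05,B001.
M06,B001.
M07,B001.
M08,B001.
M09,B001.
M10,B001.
M11,B001.
M12,B001.
M13,B001.
M14,B001.
M15,B001.
M16,B001.
M17,B001.
M18,B001.
M19,B001.
M20,B001.
M21,B001.
M22,B001.
M23,B001.
M24,B001.
M25,B001.
M26,B001.
M27,B001.
M28,B001.
M29,B001.
M30,B001.
M31,B001.
M32,B001.
M33,B001.
M34,B001.
M35,B001.
M36,B001.
M37,B001.
M38,B001.
M39,B001.
M40,B001.
M41,B001.
M42,B001.
M43,B001.
M44,B001.
M45,B001.
M46,B001.
M47,B001.
M48,B001.
M49,B001.
M50,B001.
M41,R001.
M42,R001.
M43,R001.
M44,R001.
M45,R001.
M46,R001.
M47,R001.
M48,R001.
M49,R001.
M50,R001.
M05,C002.
M10,C002.
M15,C002.
M20,C002.
M25,C002.
M30,C002.
M35,C002.
M40,C002.
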