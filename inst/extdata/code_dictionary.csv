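code,description
N100.,Ankylosing spondylitis
F440.,Uveitis
R001.,Inflammatory marker raised
B001.,Routine consultation
C002.,Medication review
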