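R59489
R119018
R105494
R105492
R96316
R172551
R72448
R71730
R177267
R207525
R215855
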