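category	effective	invalid
NAMC	86.28	0
nNAMC	0	6684.53
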