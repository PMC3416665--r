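residue	coefficient
A	1.0
V	2.9
I	3.9
L	3.9
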