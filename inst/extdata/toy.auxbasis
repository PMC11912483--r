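element X
s 1.1000000000000001 1
p 0.80000000000000004 1
d 0.69999999999999996 1
element H
s 0.69999999999999996 1
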