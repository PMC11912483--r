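element X
s 8 0.45538307133986972  1.3999999999999999 0.65777554749092293
p 0.45000000000000001 1
element H
s 1.8 0.38083738842359821  0.34999999999999998 0.71407010329424658
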