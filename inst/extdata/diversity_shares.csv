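group,share
Asteraceae,0.10
monocots,0.23
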