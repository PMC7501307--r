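# synthetic curated list: the five planted features
PLNT0001
PLNT0002
PLNT0003
PLNT0004
PLNT0005
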