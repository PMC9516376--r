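label,train,test
PAST,36,11
CURRENT,35,11
NON,66,16
UNKNOWN,252,63
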