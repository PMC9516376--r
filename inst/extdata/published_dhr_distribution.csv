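label,train,test
SJS,56,18
DIHS,44,3
AS,18,5
EB,32,7
NEG,323,77
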