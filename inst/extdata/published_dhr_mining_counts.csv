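label,srs_reported,confirmed_local,confirmed_other
AS,4,26,13
DIHS,16,29,149
SJS,7,9,77
EB,9,8,46
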