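quantity,y2011,y2016
Cm,0.622,0.656
Cc,0.715,0.693
Ci,0.653,0.655
Cfw,0.908,0.908
TFR,4.04,4.14
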