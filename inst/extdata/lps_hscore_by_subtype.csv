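subtype,low,high
well_differentiated,10,0
dedifferentiated,57,15
myxoid,26,39
pleomorphic,30,4
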