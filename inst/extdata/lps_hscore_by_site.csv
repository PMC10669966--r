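site,low,high
limb,50,33
retroperitoneal,39,9
trunk,25,11
abdomen,8,3
head,1,2
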