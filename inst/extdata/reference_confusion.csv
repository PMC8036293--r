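"",mild,moderate,severe,normal
mild,48,2,0,8
moderate,2,66,2,0
severe,0,0,40,0
normal,2,2,0,96
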