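class,total,TP,FN,TN,FP
mild,58,48,10,NA,NA
moderate,70,70,0,NA,NA
severe,40,40,0,NA,NA
normal,100,96,4,96,4
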